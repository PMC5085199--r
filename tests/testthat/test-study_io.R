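test_that("median/range conversion reproduces the banded formulas", {
  # large-n band: symmetric range, sd = (b-a)/6
  out <- hozo_convert(5, 1, 9, 100)
  expect_equal(out$mean, 5)
  expect_equal(out$sd, 8 / 6)
  # middle band: sd = (b-a)/4
  out <- hozo_convert(5, 1, 9, 40)
  expect_equal(out$mean, 5)
  expect_equal(out$sd, 2)
  # small band: a - 2m + b = 0 here, so sd = sqrt(64/12)
  out <- hozo_convert(5, 1, 9, 12)
  expect_equal(out$mean, 5)
  expect_equal(out$sd, sqrt(64 / 12))
  # band boundaries: closed left band
  expect_equal(hozo_convert(5, 1, 9, 15)$sd, sqrt(64 / 12))
  expect_equal(hozo_convert(5, 1, 9, 16)$sd, 2)
  expect_equal(hozo_convert(5, 1, 9, 70)$sd, 2)
  expect_equal(hozo_convert(5, 1, 9, 71)$sd, 8 / 6)
})

test_that("conversion mean is translation-equivariant and exact for symmetric summaries", {
  set.seed(11)
  for (rep in 1:20) {
    a <- runif(1, 0.1, 2); b <- a + runif(1, 0.5, 5)
    m <- runif(1, a, b); n <- sample(c(5, 30, 200), 1)
    c0 <- runif(1, 0.5, 3)
    base <- hozo_convert(m, a, b, n)
    shifted <- hozo_convert(m + c0, a + c0, b + c0, n)
    expect_equal(shifted$mean, base$mean + c0)
    expect_equal(shifted$sd, base$sd)
    sym <- hozo_convert((a + b) / 2, a, b, n)
    expect_equal(sym$mean, (a + b) / 2)
  }
})

test_that("degenerate and disordered ranges are rejected", {
  expect_error(hozo_convert(5, 5, 5, 100), "degenerate")
  expect_error(hozo_convert(1, 2, 9, 10), "ordering")
  expect_error(hozo_convert(5, 1, 4, 10), "ordering")
})

make_rom_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

base_rows <- data.frame(
  study_id = c("a1", "b2", "c3"),
  label = c("Alpha 2001", "Beta 2005", "Gamma 2010"),
  ethnicity = c("asian", "CAUCASIAN", "Other"),
  age_group = c("Adult", "adult", "children"),
  design = c("retrospective_cross_sectional", "other", "other"),
  quality_score = c(7, 8, 6),
  n_case = c(150, 300, 600),
  n_control = c(200, 400, 900),
  mean_case = c(1.8, 2.1, 1.5),
  sd_case = c(1.1, 1.4, 0.9),
  mean_control = c(1.2, 1.6, 1.3),
  sd_control = c(0.8, 1.0, 0.7),
  stringsAsFactors = FALSE
)

test_that("a well-formed table yields validated records with derived size classes", {
  tab <- read_study_table(make_rom_csv(base_rows), "rom")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$size_class, c("small", "moderate", "large"))
  expect_equal(tab$ethnicity, c("Asian", "Caucasian", "Other"))
  expect_equal(tab$age_group, c("adult", "adult", "children"))
  expect_true(all(is.na(tab$tnm_stage)))  # absent optionals are explicit missing
})

test_that("invariant violations are rejected with row diagnostics", {
  bad <- base_rows; bad$sd_case[2] <- 0
  expect_error(read_study_table(make_rom_csv(bad), "rom"),
               "row\\(s\\) 2.*sd_case.*strictly positive")
  bad <- base_rows; bad$n_case[1] <- 0
  expect_error(read_study_table(make_rom_csv(bad), "rom"), "row\\(s\\) 1")
  bad <- base_rows; bad$study_id[2] <- "a1"
  expect_error(read_study_table(make_rom_csv(bad), "rom"), "duplicate study_id")
  bad <- base_rows; bad$ethnicity[3] <- "martian"
  expect_error(read_study_table(make_rom_csv(bad), "rom"), "martian")
  bad <- base_rows[setdiff(names(base_rows), "n_control")]
  expect_error(read_study_table(make_rom_csv(bad), "rom"), "n_control")
})

test_that("a supplied size_class column is recomputed with a warning on mismatch", {
  rows <- base_rows
  rows$size_class <- c("large", "moderate", "large")  # first is wrong
  expect_warning(tab <- validate_rom_table(rows), "size_class")
  expect_equal(tab$size_class, c("small", "moderate", "large"))
})

test_that("median/min/max tables convert through the same formulas as hozo_convert", {
  rows <- base_rows[setdiff(names(base_rows),
                            c("mean_case", "sd_case", "mean_control", "sd_control"))]
  rows$median_case <- c(2.0, 2.2, 1.6); rows$min_case <- c(0.4, 0.5, 0.2)
  rows$max_case <- c(6.0, 8.0, 5.0)
  rows$median_control <- c(1.4, 1.7, 1.2); rows$min_control <- c(0.3, 0.4, 0.2)
  rows$max_control <- c(4.0, 5.5, 4.2)
  tab <- read_study_table(make_rom_csv(rows), "rom", convert_median = TRUE)
  expected <- hozo_convert(rows$median_case, rows$min_case, rows$max_case, rows$n_case)
  expect_equal(tab$mean_case, expected$mean)
  expect_equal(tab$sd_case, expected$sd)
})

test_that("tables written by the report writer re-read equal field by field", {
  tab <- read_study_table(make_rom_csv(base_rows), "rom")
  p <- tempfile(fileext = ".csv")
  write_study_table(tab, p)
  again <- read_study_table(p, "rom")
  expect_equal(again, tab)
  # tab-delimited round trip too
  write_study_table(tab, p, sep = "\t")
  expect_equal(read_study_table(p, "rom"), tab)
})

test_that("category-count tables parse into contiguous-bin records", {
  long <- data.frame(
    study_id = rep("a1", 3),
    bin_low = c(0, 0.4, 4.2), bin_high = c(0.4, 4.2, Inf),
    case_count = c(5, 80, 15), control_count = c(40, 150, 10))
  p <- tempfile(fileext = ".csv")
  write.csv(long, p, row.names = FALSE, quote = FALSE)
  cats <- read_study_table(p, "categories")
  expect_length(cats, 1)
  expect_equal(cats$a1$bin_edges, c(0, 0.4, 4.2, Inf))
  expect_equal(cats$a1$case_counts, c(5L, 80L, 15L))
  # non-contiguous bins rejected
  long$bin_low[3] <- 5
  write.csv(long, p, row.names = FALSE, quote = FALSE)
  expect_error(read_study_table(p, "categories"), "contiguous")
})

test_that("diagnostic tables validate counts and cut-off bands", {
  d <- data.frame(study_id = c("x", "y"), cutoff_group = c("LT0.5", "gt3.5"),
                  tp = c(10, 5), fp = c(4, 2), fn = c(3, 20), tn = c(40, 60))
  p <- tempfile(fileext = ".csv")
  write.csv(d, p, row.names = FALSE, quote = FALSE)
  tab <- read_study_table(p, "diagnostic")
  expect_equal(tab$cutoff_group, c("lt0.5", "gt3.5"))
  d$tp[1] <- -1
  write.csv(d, p, row.names = FALSE, quote = FALSE)
  expect_error(read_study_table(p, "diagnostic"), "non-negative")
})
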