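test_that("reads comma and tab tables with ids, headers optional", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,p", "g1,0.01", "", "g2,0.2", "g3,0.9"), f)
  pv <- read_pvalue_table(f)
  expect_equal(pv$id, c("g1", "g2", "g3"))   # blank line skipped
  expect_equal(pv$p, c(0.01, 0.2, 0.9))

  t <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tpval\textra", "a\t0.3\t1.0", "b\t0.6\t2.0"), t)
  pv2 <- read_pvalue_table(t, column = "pval")
  expect_equal(pv2$p, c(0.3, 0.6))
  expect_equal(pv2$id, c("a", "b"))

  h <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0.04", "0.5"), h)
  pv3 <- read_pvalue_table(h)
  expect_equal(pv3$p, c(0.04, 0.5))
  expect_equal(pv3$id, c("test_1", "test_2"))  # generated ids
})

test_that("read errors name the offending file row", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,p", "g1,0.01", "g2,NA", "g3,0.5"), f)
  expect_error(read_pvalue_table(f), "row 3", class = "mt_data_error")

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,p", "g1,0.2", "g2,1.7"), g)
  expect_error(read_pvalue_table(g), "out of range", class = "mt_data_error")

  expect_error(read_pvalue_table(withr::local_tempfile(fileext = ".csv")),
               "not found", class = "mt_data_error")
  e <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,p", e)
  expect_error(read_pvalue_table(e), "empty", class = "mt_data_error")
})

test_that("results round-trip through CSV at better than 1e-12", {
  res <- adjust_pvalues(data.frame(p = c(1/3, 0.0123456789012345, 0.9)),
                        method = "holm")
  f <- withr::local_tempfile(fileext = ".csv")
  write_results(res, f)
  back <- utils::read.csv(f, comment.char = "#")
  expect_equal(back$p_raw, res$p, tolerance = 1e-13)
  expect_equal(back$adjusted, res$p_adjusted, tolerance = 1e-13)
  expect_equal(back$rejected, res$rejected)
  expect_equal(unique(back$method), "holm")

  # empty rejection set still produces rows
  none <- adjust_pvalues(data.frame(p = c(0.9, 0.95)), method = "bonferroni")
  write_results(none, f)
  back2 <- utils::read.csv(f, comment.char = "#")
  expect_equal(nrow(back2), 2L)
  expect_false(any(back2$rejected))
})

test_that("q-value output carries pi0 provenance in the comment header", {
  qv <- qvalues(data.frame(p = c(0.01, 0.3, 0.6, 0.8)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_results(qv, f)
  header <- grep("^#", readLines(f), value = TRUE)
  expect_true(any(grepl("pi0", header)))
  expect_true(any(grepl("count_above_half", header)))
  back <- utils::read.csv(f, comment.char = "#")
  expect_true("q_value" %in% names(back))
})

test_that("recommender covers the published scenarios and is total", {
  r1 <- recommend_method(exploratory = FALSE, n_tests = 10,
                         dependent = FALSE, tolerate_false_positives = FALSE)
  expect_equal(r1$family, "fwer")
  expect_equal(r1$method, "holm")

  r2 <- recommend_method(exploratory = TRUE, n_tests = 20000,
                         dependent = FALSE, tolerate_false_positives = TRUE)
  expect_equal(r2$method, "bh")

  r3 <- recommend_method(exploratory = TRUE, n_tests = 20000,
                         dependent = TRUE, tolerate_false_positives = TRUE)
  expect_equal(r3$method, "by")

  # intolerance of false positives forces FWER control regardless of n
  r4 <- recommend_method(exploratory = TRUE, n_tests = 50000,
                         dependent = TRUE, tolerate_false_positives = FALSE)
  expect_equal(r4$family, "fwer")

  # totality: every answer combination yields exactly one implemented method
  grid <- expand.grid(exploratory = c(TRUE, FALSE),
                      n_tests = c(5, 300, 301, 1e5),
                      dependent = c(TRUE, FALSE),
                      tolerant = c(TRUE, FALSE))
  for (i in seq_len(nrow(grid))) {
    rec <- recommend_method(grid$exploratory[i], grid$n_tests[i],
                            grid$dependent[i], grid$tolerant[i])
    expect_length(rec$method, 1L)
    expect_true(rec$method %in% c("bonferroni", "sidak", "holm", "hochberg",
                                  "hochberg_rank", "bh", "by", "qvalue"))
    # the traversal path reproduces the answers given
    path <- rec$path[[1]]
    expect_gt(nrow(path), 1L)
    expect_equal(path$answer[1], as.character(grid$exploratory[i]))
  }
})

test_that("CLI adjust matches direct library calls and logs to stderr", {
  input <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,p", "a,0.016", "b,0.2", "c,0.8"), input)
  output <- withr::local_tempfile(fileext = ".csv")
  code <- suppressMessages(cli_main(c("adjust", "--method", "bonferroni",
                                      "--input", input, "--output", output)))
  expect_identical(code, 0L)
  got <- utils::read.csv(output, comment.char = "#")
  expect_equal(got$adjusted[1], 0.048, tolerance = 1e-12)
  expect_true(got$rejected[1])
  direct <- adjust_pvalues(read_pvalue_table(input), method = "bonferroni")
  expect_equal(got$adjusted, direct$p_adjusted, tolerance = 1e-13)
  expect_equal(got$rejected, direct$rejected)
  expect_message(cli_main(c("adjust", "--method", "holm", "--input", input,
                            "--output", output)), "rejected=")
})

test_that("CLI exit codes distinguish usage and data errors", {
  input <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,p", "a,0.016"), input)
  output <- withr::local_tempfile(fileext = ".csv")
  # unknown method: usage error listing the valid methods
  expect_message(
    code <- cli_main(c("adjust", "--method", "nope", "--input", input,
                       "--output", output)),
    "valid methods")
  expect_identical(code, 1L)
  expect_identical(suppressMessages(cli_main(c("frobnicate"))), 1L)
  expect_identical(suppressMessages(cli_main(character(0))), 0L)  # usage text
  # unreadable input: data error
  expect_identical(
    suppressMessages(cli_main(c("adjust", "--method", "bh", "--input",
                                "no_such_file.csv", "--output", output))),
    2L)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,p", "a,2.5"), bad)
  expect_identical(
    suppressMessages(cli_main(c("adjust", "--method", "bh", "--input", bad,
                                "--output", output))),
    2L)
})

test_that("CLI qvalue output keeps the pi0 header; simulate is seed-stable", {
  input <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,p", sprintf("g%d,%.4f", 1:20, seq(0.001, 0.95,
                                                     length.out = 20))),
             input)
  output <- withr::local_tempfile(fileext = ".csv")
  code <- suppressMessages(
    cli_main(c("adjust", "--method", "qvalue", "--pi0-estimator",
               "twice_mean_p", "--input", input, "--output", output)))
  expect_identical(code, 0L)
  lines <- readLines(output)
  expect_true(any(grepl("pi0", lines[startsWith(lines, "#")])))
  expect_true(any(grepl("twice_mean_p", lines)))

  out1 <- withr::local_tempfile(fileext = ".csv")
  out2 <- withr::local_tempfile(fileext = ".csv")
  for (o in c(out1, out2)) {
    expect_identical(suppressMessages(
      cli_main(c("simulate", "--seed", "7", "--m", "40", "--reps", "50",
                 "--pi0", "0.8", "--effect", "3", "--output", o))), 0L)
  }
  expect_identical(readLines(out1), readLines(out2))

  expect_identical(suppressMessages(
    cli_main(c("recommend", "--exploratory", "--independent", "--tolerant",
               "--n-tests", "5000", "--log-level", "quiet"))), 0L)
})
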