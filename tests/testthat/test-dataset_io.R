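test_that("pIC50 transform follows the molar convention and rejects bad input", {
  expect_equal(to_pic50(1000), 6)
  expect_equal(to_pic50(1), 9)
  expect_equal(to_pic50(50), 7.30103, tolerance = 1e-6)
  expect_error(to_pic50(0), "positive")
  expect_error(to_pic50(-5), "positive")
  expect_error(to_pic50(NA_real_), "positive|finite")
  # strictly decreasing in IC50
  x <- sort(10^runif(20, -2, 5))
  expect_true(all(diff(to_pic50(x)) < 0))
})

test_that("activity loading filters bad rows, tallies rejections and refuses duplicates", {
  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(
    compound_id = c("a", "b", "c"), smiles = "CCO",
    target_id = "HDAC2", ic50_nm = c(10, 0, 250)),
    tmp, row.names = FALSE)
  rec <- read_activities(tmp, quiet = TRUE)
  expect_equal(nrow(rec), 2L)
  expect_equal(sum(attr(rec, "rejections")), 1L)
  expect_equal(rec$pic50, 9 - log10(c(10, 250)))
  expect_true(all(rec$split == "unassigned"))

  write.csv(data.frame(
    compound_id = c("a", "a"), smiles = "CCO",
    target_id = "HDAC2", ic50_nm = c(10, 20)),
    tmp, row.names = FALSE)
  expect_error(read_activities(tmp, quiet = TRUE), "duplicate")

  write.csv(data.frame(
    compound_id = c("a", "b", "c"), smiles = c("CCO", "C((C", "CCN"),
    target_id = c("HDAC2", "HDAC2", "NOTATARGET"),
    ic50_nm = c(10, 10, 10)),
    tmp, row.names = FALSE)
  rec <- read_activities(tmp, quiet = TRUE)
  expect_equal(nrow(rec), 1L)
  rej <- attr(rec, "rejections")
  expect_equal(unname(rej[["implausible_smiles"]]), 1L)
  expect_equal(unname(rej[["unknown_target"]]), 1L)

  write.csv(data.frame(compound_id = "a", smiles = "CCO",
                       target_id = "HDAC2", ic50_nm = -1),
            tmp, row.names = FALSE)
  expect_error(read_activities(tmp, quiet = TRUE), "no valid")
  expect_error(read_activities(tempfile(), quiet = TRUE), "not found")
})

test_that("stratified split takes floor(fraction * n) per stratum and partitions it", {
  set.seed(42)
  sizes <- c(531, 197, 10, 46, 7, 3)
  rec <- do.call(rbind, lapply(seq_along(sizes), function(i)
    data.frame(compound_id = paste0("t", i, "_", seq_len(sizes[i])),
               smiles = NA, target_id = paste0("T", i),
               ic50_nm = 100, pic50 = 7, y_scaled = NA_real_,
               split = "unassigned", stringsAsFactors = FALSE)))
  out <- stratified_split(rec, 0.65, seed = 11)
  ss <- split_summary(out)
  got <- setNames(ss$n_train, ss$target_id)
  expect_equal(unname(got[paste0("T", seq_along(sizes))]),
               floor(0.65 * sizes))
  expect_equal(ss$n_train + ss$n_test, ss$total)
  expect_true(all(out$split %in% c("train", "test")))
  # |n_train - 0.65 n| < 1 for every stratum
  expect_true(all(abs(ss$n_train - 0.65 * ss$total) < 1))
  # different seeds permute membership but keep the counts
  out2 <- stratified_split(rec, 0.65, seed = 12)
  expect_equal(split_summary(out2)$n_train, ss$n_train)
  expect_false(identical(out$split, out2$split))
  expect_error(stratified_split(rec, 1.2), "between 0 and 1")
  expect_error(stratified_split(out, 0.65), "already")
})

test_that("response scaling standardizes pIC50 and round-trips exactly", {
  rec <- data.frame(compound_id = c("a", "b"), smiles = NA,
                    target_id = "T1", ic50_nm = 1,
                    pic50 = c(5, 7), y_scaled = NA_real_, split = "train",
                    stringsAsFactors = FALSE)
  out <- scale_response(rec, fit_on = "all")
  expect_equal(out$y_scaled, c(-1, 1) / sqrt(2), tolerance = 1e-7)
  sc <- attr(out, "response_scaling")
  expect_equal(unscale_response(out$y_scaled, sc), out$pic50,
               tolerance = 1e-10)

  # fitting on the training subset only: test rows use train statistics
  rec2 <- data.frame(compound_id = letters[1:4], smiles = NA,
                     target_id = "T1", ic50_nm = 1,
                     pic50 = c(5, 7, 100, 200), y_scaled = NA_real_,
                     split = c("train", "train", "test", "test"),
                     stringsAsFactors = FALSE)
  out2 <- scale_response(rec2, fit_on = "train")
  expect_equal(out2$y_scaled[1:2], c(-1, 1) / sqrt(2), tolerance = 1e-7)
  expect_equal(out2$y_scaled[3], (100 - 6) / sqrt(2), tolerance = 1e-7)

  rec$pic50 <- c(6, 6)
  expect_error(scale_response(rec, fit_on = "all"), "degenerate")
})

test_that("split records survive a CSV round trip", {
  rec <- data.frame(compound_id = c("a", "b"), smiles = "CCO",
                    target_id = "HDAC2", ic50_nm = c(10, 20),
                    pic50 = 9 - log10(c(10, 20)), y_scaled = NA_real_,
                    split = c("train", "test"), stringsAsFactors = FALSE)
  tmp <- tempfile(fileext = ".csv")
  write_activities(rec, tmp)
  back <- read.csv(tmp, stringsAsFactors = FALSE)
  expect_equal(back$split, c("train", "test"))
  expect_equal(back$ic50_nm, c(10, 20))
})
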