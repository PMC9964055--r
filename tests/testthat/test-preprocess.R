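test_that("the retention filter is conjunctive over pH", {
  tb <- tibble::tibble(
    compound_id = c("below_everywhere", "saved_by_one_ph"),
    rt_pH2.7 = c(1.2, 1.2), rt_pH3.5 = c(1.5, 2.5), rt_pH5 = c(1.1, 1.1),
    rt_pH6.5 = c(1.0, 1.0), rt_pH8 = c(1.9, 1.9)
  )
  out <- filter_low_retention(tb)
  expect_equal(out$compound_id, "saved_by_one_ph")
  expect_equal(attr(out, "removed"), "below_everywhere")

  tb$rt_pH5[1] <- NA
  expect_error(filter_low_retention(tb), "below_everywhere")
})

test_that("filter survivors match an exhaustive recount on random tables", {
  withr::with_seed(88, {
    rt <- matrix(runif(200 * 5, 0, 6), 200, 5)
    tb <- dplyr::bind_cols(
      tibble::tibble(compound_id = sprintf("c%03d", 1:200)),
      tibble::as_tibble(rt, .name_repair = "minimal") |>
        stats::setNames(sprintf("rt_pH%g", c(2.7, 3.5, 5, 6.5, 8)))
    )
    out <- filter_low_retention(tb, threshold = 2)
    # brute force: loop compound by compound
    keep <- logical(200)
    for (i in 1:200) keep[i] <- any(rt[i, ] >= 2)
    expect_equal(nrow(out), sum(keep))
    expect_equal(out$compound_id, tb$compound_id[keep])
  })
})

test_that("zero-variance removal drops exactly the constant columns", {
  withr::with_seed(3, {
    X <- matrix(rnorm(50 * 8), 50, 8,
                dimnames = list(NULL, sprintf("d%d", 1:8)))
    X[, c(2, 5, 7)] <- rep(c(3, 0, -1), each = 50)
    out <- remove_zero_variance(X)
    expect_equal(sort(attr(out, "dropped")), c("d2", "d5", "d7"))
    expect_equal(ncol(out), 5L)

    two_vals <- matrix(rep(c(0, 1), 10), 20, 1, dimnames = list(NULL, "b"))
    expect_equal(ncol(remove_zero_variance(cbind(X[1:20, 1, drop = FALSE],
                                                 two_vals))), 2L)
    expect_error(remove_zero_variance(matrix(1, 5, 2)), "zero variance")
  })
})

test_that("standardization centers and scales on train parameters only", {
  withr::with_seed(11, {
    tr <- matrix(rnorm(40 * 6, mean = 5, sd = 3), 40, 6,
                 dimnames = list(NULL, sprintf("f%d", 1:6)))
    te <- matrix(rnorm(10 * 6, mean = 5, sd = 3), 10, 6,
                 dimnames = list(NULL, sprintf("f%d", 1:6)))
    te[1, ] <- tr[7, ]   # a test row equal to a train row
    std <- standardize(tr, te)
    expect_lt(max(abs(colMeans(std$train))), 1e-10)
    expect_lt(max(abs(apply(std$train, 2, sd) - 1)), 1e-10)
    expect_equal(std$test[1, ], std$train[7, ], tolerance = 1e-12)

    back <- unstandardize(std$train, std$scaler)
    expect_lt(max(abs(back - tr)), 1e-10)

    tr0 <- cbind(tr, const = 1)
    expect_error(standardize(tr0), "remove_zero_variance")
  })
})

test_that("scaler parameters never see the test rows", {
  withr::with_seed(12, {
    tr <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, letters[1:4]))
    te1 <- matrix(rnorm(5 * 4), 5, 4, dimnames = list(NULL, letters[1:4]))
    te2 <- te1 + 100   # wildly different external set
    s1 <- standardize(tr, te1)$scaler
    s2 <- standardize(tr, te2)$scaler
    expect_identical(s1, s2)
  })
})

test_that("the split reproduces the 77 -> 67 + 10 flow and is seeded", {
  ds <- qsrr_simulate(qsrr_sim_config(seed = 55))
  filt <- filter_low_retention(ds$compound_table)
  expect_equal(nrow(filt), 77L)
  mats <- lapply(ds$descriptors, function(m) {
    remove_zero_variance(m[match(filt$compound_id, m$compound_id), ])
  })
  sp <- split_dataset(filt, mats, n_test = 10, seed = 3)
  expect_length(sp$train_ids, 67L)
  expect_length(sp$test_ids, 10L)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0L)

  # identical membership across runs and across pH
  sp2 <- split_dataset(filt, mats, n_test = 10, seed = 3)
  expect_identical(sp$test_ids, sp2$test_ids)
  for (e in sp$per_ph) {
    expect_identical(rownames(e$test_X), sp$test_ids)
    expect_identical(colnames(e$train_X), colnames(e$test_X))
  }

  expect_error(split_dataset(filt, mats, n_test = 80, seed = 1), "n_test")
})

test_that("stratified splits balance retention quartiles within one compound", {
  ds <- qsrr_simulate(qsrr_sim_config(seed = 56))
  filt <- filter_low_retention(ds$compound_table)
  mats <- lapply(ds$descriptors, function(m) {
    remove_zero_variance(m[match(filt$compound_id, m$compound_id), ])
  })
  sp <- split_dataset(filt, mats, n_test = 12, seed = 4, stratify = TRUE)
  mean_rt <- rowMeans(as.matrix(filt[grep("^rt_pH", names(filt))]))
  names(mean_rt) <- filt$compound_id
  q <- quantile(mean_rt, c(0.25, 0.5, 0.75))
  counts <- table(findInterval(mean_rt[sp$test_ids], q))
  expect_true(all(abs(counts - 3) <= 1))
})

test_that("forced compounds always land in the external set", {
  ds <- small_dataset(seed = 61)
  filt <- filter_low_retention(ds$compound_table)
  mats <- lapply(ds$descriptors, function(m) {
    remove_zero_variance(m[match(filt$compound_id, m$compound_id), ])
  })
  forced <- filt$compound_id[5]
  sp <- split_dataset(filt, mats, n_test = 6, seed = 1, force_test = forced)
  expect_true(forced %in% sp$test_ids)
  expect_error(split_dataset(filt, mats, n_test = 6, seed = 1,
                             force_test = "nope"), "nope")
})

test_that("log transform round-trips through back_transform", {
  ds <- small_dataset(seed = 62)
  sp <- small_split(ds)
  e <- sp$per_ph[[1L]]
  obs_min <- ds$compound_table$rt_pH2.7[
    match(sp$test_ids, ds$compound_table$compound_id)]
  expect_equal(unname(back_transform(e$test_y, e$transform)),
               unname(obs_min), tolerance = 1e-12)
})
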