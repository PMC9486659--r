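test_that("Youden's J follows its definition and range checks", {
  expect_equal(youden(0.93, 0.94), 0.87, tolerance = 1e-12)
  expect_equal(youden(1, 1), 1)
  expect_equal(youden(0.3, 0.7), 0, tolerance = 1e-12)
  expect_error(youden(1.2, 0.5), "\\[0, 1\\]")
})

test_that("threshold segmentation marks in-mask voxels below the threshold", {
  dims <- c(3, 3, 1)
  map <- array(c(0.50, 2.5, 0.7, 0.6, 0.619, 0.621, 1, 2, 3), dims)
  mask <- array(1L, dims); mask[3, 3, 1] <- 0L
  seg <- threshold_segment(map, 0.620, mask)
  expect_equal(seg[1, 1, 1], 1L)   # ADC 0.50 < 0.620: infarct
  expect_equal(seg[2, 1, 1], 0L)   # D_ax_intra 2.5 at tau 2.0 analogue
  expect_equal(seg[2, 2, 1], 1L)
  expect_equal(seg[3, 2, 1], 0L)
  expect_equal(sum(threshold_segment(map, -Inf, mask)), 0)
  expect_equal(sum(threshold_segment(map, Inf, mask)), sum(mask))
  expect_error(threshold_segment(map, 1, array(1L, c(2, 2, 1))), "shapes")
})

test_that("mask algebra obeys set laws", {
  set.seed(13)
  dims <- c(5, 4, 3)
  a <- array(as.integer(stats::runif(prod(dims)) > 0.6), dims)
  b <- array(as.integer(stats::runif(prod(dims)) > 0.6), dims)
  expect_identical(combine_masks(a, a, "union"), a)
  expect_identical(combine_masks(a, a, "intersection"), a)
  un <- combine_masks(a, b, "union")
  it <- combine_masks(a, b, "intersection")
  expect_true(all(it <= un))
  expect_equal(sum(un) + sum(it), sum(a) + sum(b))  # inclusion-exclusion
  disj <- array(0L, dims); disj[1, 1, 1] <- 1L
  a0 <- a; a0[1, 1, 1] <- 0L
  expect_equal(sum(combine_masks(a0, disj, "union")), sum(a0) + 1)
  expect_error(combine_masks(a, b, "xor"), "arg")
})

test_that("mirroring reflects across the x midline and clips", {
  dims <- c(10, 6, 4)
  m <- array(0L, dims)
  m[4, 2, 3] <- 1L   # 0-based x = 3 -> mirrored 0-based x = 6 (1-based 7)
  mm <- mirror_mask(m)
  expect_equal(which(mm > 0), which(array(seq_len(prod(dims)), dims) ==
                                      ((3 - 1) * 10 * 6 + (2 - 1) * 10 + 7)))
  expect_equal(sum(mm), sum(m))  # bijection preserves counts
  # midline-symmetric mask is a fixed point
  sym <- array(0L, dims); sym[c(3, 8), 4, 2] <- 1L
  expect_identical(mirror_mask(sym), sym)
  # clipping intersects
  clip <- array(0L, dims)
  expect_equal(sum(mirror_mask(m, clip)), 0)
})

test_that("pooled ROC matches the pairwise concordance oracle exactly", {
  # small handcrafted set with ties
  score <- c(0.1, 0.2, 0.2, 0.4, 0.3, 0.2, 0.5, 0.9)
  truth <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  r <- pooled_roc(array(score, c(8, 1, 1)), array(as.integer(truth), c(8, 1, 1)))
  conc <- 0
  for (i in which(truth)) for (j in which(!truth))
    conc <- conc + (score[i] < score[j]) + 0.5 * (score[i] == score[j])
  expect_equal(r$auc, conc / (4 * 4), tolerance = 1e-12)

  # random instances, exact equality under the tie convention
  set.seed(99)
  for (rep in 1:10) {
    n <- 200
    sc <- round(stats::rnorm(n), 1)          # coarse rounding forces ties
    tr <- stats::runif(n) < 0.3
    if (!any(tr) || all(tr)) next
    r2 <- pooled_roc(array(sc, c(n, 1, 1)), array(as.integer(tr), c(n, 1, 1)))
    cc <- mean(outer(sc[tr], sc[!tr], "<") + 0.5 * outer(sc[tr], sc[!tr], "=="))
    expect_equal(r2$auc, cc, tolerance = 1e-12)
  }
})

test_that("ROC endpoints behave at separation and at chance", {
  les <- array(c(rep(1L, 10), rep(0L, 20)), c(30, 1, 1))
  sep <- array(c(stats::runif(10, 0, 1), stats::runif(20, 2, 3)), c(30, 1, 1))
  r <- pooled_roc(sep, les)
  expect_equal(r$auc, 1.0)
  expect_equal(r$j_max, 1.0)
  expect_equal(r$sens_at_opt, 1.0)
  expect_equal(r$spec_at_opt, 1.0)
  # identical empirical score distributions in both classes: exactly chance
  same <- array(c(rep(1:5, 2), rep(1:5, 4)), c(30, 1, 1))
  r2 <- pooled_roc(same, les)
  expect_equal(r2$auc, 0.5, tolerance = 1e-12)
  expect_error(pooled_roc(sep, array(0L, c(30, 1, 1))), "no lesion")
})

test_that("pooled ROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  sc <- stats::rnorm(500) + rep(c(0, -1), c(350, 150))
  tr <- rep(c(0L, 1L), c(350, 150))
  r <- pooled_roc(array(sc, c(500, 1, 1)), array(tr, c(500, 1, 1)))
  ref <- pROC::roc(tr, sc, direction = ">", quiet = TRUE)  # lesion = lower
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
})

test_that("pooled ROC is invariant to subject order and internal J is consistent", {
  set.seed(8)
  mk <- function(n, mu) list(score = array(stats::rnorm(n, mu), c(n, 1, 1)),
                             truth = array(as.integer(stats::runif(n) < .3), c(n, 1, 1)))
  s1 <- mk(80, 0); s2 <- mk(120, 0.4); s3 <- mk(50, -0.2)
  ra <- pooled_roc(list(s1$score, s2$score, s3$score),
                   list(s1$truth, s2$truth, s3$truth))
  rb <- pooled_roc(list(s3$score, s1$score, s2$score),
                   list(s3$truth, s1$truth, s2$truth))
  expect_equal(ra$auc, rb$auc, tolerance = 1e-15)
  expect_equal(ra$optimal_threshold, rb$optimal_threshold)
  cv <- tidy(ra)
  expect_equal(ra$j_max, max(cv$sensitivity + cv$specificity - 1),
               tolerance = 1e-12)
  expect_equal(glance(ra)$j_max, youden(ra$sens_at_opt, ra$spec_at_opt),
               tolerance = 1e-12)
})

test_that("lesion statistics follow the linear-interpolation convention", {
  dims <- c(100, 2, 1)
  mask <- array(1L, dims)
  vals <- array(rep(1:100, 2), dims)
  fields <- list(v_intra = vals / 300, v_extra = 1 - vals / 300 - 0.1 + vals * 0,
                 v_csf = array(0.1, dims),
                 d_ax_intra = vals / 50, d_ax_extra = vals / 100,
                 d_rad_extra = vals / 200)
  maps <- parameter_maps(fields, mask, check = FALSE)
  les <- array(0L, dims); les[, 1, 1] <- 1L
  con <- array(0L, dims); con[, 2, 1] <- 1L
  st <- lesion_statistics(maps, les, con)
  row <- st[st$parameter == "d_ax_intra" & st$region == "lesion", ]
  expect_equal(row$p5, 5.95 / 50, tolerance = 1e-12)
  expect_equal(row$p95, 95.05 / 50, tolerance = 1e-12)
  expect_equal(row$mean, mean(1:100) / 50, tolerance = 1e-12)
  # constant map: mean = p5 = p95
  rowc <- st[st$parameter == "v_csf" & st$region == "contralateral", ]
  expect_equal(rowc$mean, 0.1); expect_equal(rowc$p5, 0.1)
  expect_equal(rowc$p95, 0.1)
  expect_error(lesion_statistics(maps, array(0L, dims), con), "empty")
})

test_that("variant evaluation emits the full report with consistent J", {
  set.seed(17)
  dims <- c(12, 12, 4)
  brain <- array(1L, dims)
  dmi_t <- array(0L, dims); dmi_t[3:6, 3:6, 2] <- 1L
  dwi_t <- array(0L, dims); dwi_t[4:7, 3:6, 2] <- 1L
  dmap <- array(stats::rnorm(prod(dims), 2.5, 0.2), dims)
  dmap[dmi_t > 0] <- stats::rnorm(sum(dmi_t), 1.6, 0.2)
  amap <- array(stats::rnorm(prod(dims), 0.75, 0.05), dims)
  amap[dwi_t > 0] <- stats::rnorm(sum(dwi_t), 0.5, 0.05)
  tab <- evaluate_variants(list(d_ax_intra = dmap, adc = amap),
                           dmi_t, dwi_t, brain)
  expect_equal(nrow(tab), 8)
  expect_setequal(unique(tab$ground_truth_variant),
                  c("dmi", "dwi", "intersection", "union"))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  expect_equal(tab$j_max, tab$sens + tab$spec - 1, tolerance = 1e-12)
  td <- withr::local_tempdir()
  p <- file.path(td, "report.csv")
  write_roc_table(tab, p)
  back <- readr::read_csv(p, show_col_types = FALSE)
  expect_equal(nrow(back), 8)
  expect_equal(back$auc, tab$auc, tolerance = 1e-12)
})
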