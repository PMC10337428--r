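test_that("cross-tab counts partition the cohort for every algorithm", {
  coh <- cached_default_cohort()
  set.seed(8)
  sub <- coh[sample(nrow(coh), 2000), ]
  tri <- triage_all(sub)
  ct <- triage_crosstab(sub, tri)
  for (a in c("start", "rts", "life")) for (bt in c("niss", "rts")) {
    sel <- ct$algorithm == a & ct$band_type == bt
    expect_identical(sum(ct$n[sel]), 2000L)
    expect_equal(sum(ct$pct[sel]), 100)
  }
  # calibrated LIFE triage never puts NISS > 25 in green
  life_green_high <- ct$algorithm == "life" & ct$category == "green" &
    ct$band_type == "niss" & ct$band %in% c("25-40", "40-75")
  expect_true(all(ct$n[life_green_high] == 0))
  expect_error(triage_crosstab(sub, tri, score_bands = list(a = 1)),
    "unknown band spec")
})

test_that("cross-tab matches a hand tally on a toy cohort", {
  pts <- data.frame(patient_id = c("a", "b", "c", "d"),
    niss = c(5L, 18L, 30L, 60L), rts = c(7.8408, 6.9, 4.2, 1.0))
  tri <- data.frame(patient_id = pts$patient_id,
    life = factor(c("green", "yellow", "red", "black"),
      levels = triage_levels()))
  ct <- triage_crosstab(pts, tri)
  pick <- function(cat, bt, band)
    ct$n[ct$category == cat & ct$band_type == bt & ct$band == band]
  expect_identical(pick("green", "niss", "1-10"), 1L)
  expect_identical(pick("yellow", "niss", "10-25"), 1L)
  expect_identical(pick("red", "niss", "25-40"), 1L)
  expect_identical(pick("black", "niss", "40-75"), 1L)
  expect_identical(pick("green", "rts", ">7.5"), 1L)
  expect_identical(pick("yellow", "rts", "5-7.5"), 1L)
  expect_identical(pick("red", "rts", "2.5-5"), 1L)
  expect_identical(pick("black", "rts", "<2.5"), 1L)
  expect_identical(sum(ct$n), 8L) # 4 patients x 2 band types
})

test_that("consensus comparison adjudicates clusters on the real cohort", {
  coh <- cached_default_cohort()
  set.seed(13)
  sub <- coh[sample(nrow(coh), 3000), ]
  tri <- triage_all(sub)
  # a cluster made of half the red-consensus patients compares as red
  # (the other half remains available as the red consensus subset)
  all_red <- which(as.character(tri$start) == "red" &
    as.character(tri$rts) == "red" & as.character(tri$life) == "red")
  expect_gt(length(all_red), 10)
  assign <- rep(2L, nrow(sub))
  assign[all_red[seq_len(floor(length(all_red) / 2))]] <- 1L
  # the default world has no three-way yellow consensus: warned + excluded
  expect_warning(
    res <- consensus_compare(sub, tri, assign, focus_cluster = 1),
    "empty consensus subset 'yellow'")
  expect_identical(res$overall, "red")
  expect_identical(unname(res$nearest["niss"]), "red")
  expect_error(suppressWarnings(consensus_compare(sub, tri, assign,
    focus_cluster = 99)), "empty")
})

test_that("consensus comparison recovers a yellow-like cluster (toy)", {
  set.seed(14)
  n <- 40
  mk <- function(id, niss, rts, cat) {
    list(p = data.frame(patient_id = id, niss = niss, rts = rts),
      t = data.frame(patient_id = id,
        start = cat, rts = cat, life = cat,
        survival_time_min = survival_time_without_treatment(rts,
          pmax(pmin(niss, 75L), 1L))))
  }
  g <- mk(sprintf("g%02d", 1:n), sample(2:8, n, TRUE), 7.8408, "green")
  y <- mk(sprintf("y%02d", 1:n), sample(12:22, n, TRUE),
    sample(c(6.904, 7.8408), n, TRUE), "yellow")
  r <- mk(sprintf("r%02d", 1:n), sample(28:45, n, TRUE),
    sample(c(5.1, 6.2), n, TRUE), "red")
  # focus cluster drawn from the yellow-consensus distribution but
  # triaged heterogeneously (categories disagree, so not consensus)
  f <- mk(sprintf("f%02d", 1:20), sample(12:22, 20, TRUE),
    sample(c(6.904, 7.8408), 20, TRUE), "yellow")
  f$t$start <- "green"
  pts <- rbind(g$p, y$p, r$p, f$p)
  tri <- rbind(g$t, y$t, r$t, f$t)
  assign <- rep(c(1L, 2L, 3L, 4L), c(n, n, n, 20))
  res <- consensus_compare(pts, tri, assign, focus_cluster = 4)
  expect_identical(res$overall, "yellow")
  expect_identical(unname(res$nearest["niss"]), "yellow")
  expect_identical(unname(res$nearest["survival_time_min"]), "yellow")
  expect_identical(sort(unique(res$consensus$category)),
    c("green", "red", "yellow"))
})

test_that("seeded subsampling before clustering is reproducible", {
  coh <- cached_default_cohort()
  pick_sub <- function(seed) {
    set.seed(seed)
    coh[sort(sample(nrow(coh), 150)), ]
  }
  s1 <- pick_sub(99)
  expect_identical(s1, pick_sub(99))
  feats <- patient_features(s1)
  d <- gower_matrix(feats)
  cl <- pam_cluster(d, 4)
  expect_identical(cl$assignments, pam_cluster(d, 4)$assignments)
  expect_true(all(cl$medoid_ids %in% s1$patient_id))
})
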