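# small null-trait pipeline shared by the threshold tests
null_pipeline <- function(seed, map = small_map(n_markers = 10, n_chr = 2),
                          n_f2 = 30, n_f3 = 90) {
  cr <- small_cross(seed = seed, n_f2 = n_f2, n_f3 = n_f3, map = map)
  sp <- list(trait_spec("t", 10, family_sd = 0.5, residual_sd = 1))
  ph <- simulate_phenotypes(cr$ped, cr$geno, cr$map, sp, seed = seed + 1)
  adj <- suppressWarnings(adjust_phenotypes(ph))
  list(cr = cr, adj = adj)
}

test_that("too few permutations for the requested alpha is an error", {
  np <- null_pipeline(1)
  expect_error(
    permutation_thresholds(np$adj, np$cr$geno, np$cr$map, n_perm = 10,
                           alpha = 0.05, seed = 1),
    "too small")
})

test_that("alpha = 1 collapses the threshold to the smallest null max", {
  np <- null_pipeline(2)
  thr <- permutation_thresholds(np$adj, np$cr$geno, np$cr$map,
                                n_perm = 25, alpha = 1, seed = 3)
  expect_equal(unname(thr$genomewide$t["mLOD"]),
               min(thr$maxima$t[, "mLOD"]))
})

test_that("thresholds are reproducible bit-exact under a seed", {
  np <- null_pipeline(3)
  t1 <- permutation_thresholds(np$adj, np$cr$geno, np$cr$map,
                               n_perm = 30, alpha = 0.1, seed = 9)
  t2 <- permutation_thresholds(np$adj, np$cr$geno, np$cr$map,
                               n_perm = 30, alpha = 0.1, seed = 9)
  expect_identical(t1, t2)
})

test_that("threshold sets round-trip through JSON", {
  np <- null_pipeline(4)
  thr <- permutation_thresholds(np$adj, np$cr$geno, np$cr$map,
                                n_perm = 25, alpha = 0.2, seed = 2)
  td <- withr::local_tempdir()
  f <- file.path(td, "thr.json")
  write_thresholds_json(thr, f)
  back <- read_thresholds_json(f)
  expect_equal(back$genomewide, thr$genomewide)
  expect_equal(back$alpha, thr$alpha)
  expect_equal(back$n_perm, thr$n_perm)
  expect_equal(back$pointwise_lod, thr$pointwise_lod)
})

test_that("QTL calling finds a strong simulated locus and is monotone", {
  map <- small_map(n_markers = 10, n_chr = 2)
  cr <- small_cross(seed = 31, n_f2 = 40, n_f3 = 160, map = map)
  sp <- list(trait_spec("t", 0,
                        qtls = list(list(chromosome = 2, position_cM = 20,
                                         a = 1.2, d = 0, i = 0)),
                        family_sd = 0.3, residual_sd = 1))
  ph <- simulate_phenotypes(cr$ped, cr$geno, map, sp, seed = 32)
  adj <- suppressWarnings(adjust_phenotypes(ph))
  scan <- genome_scan(adj, cr$geno, map)
  thr <- permutation_thresholds(adj, cr$geno, map, n_perm = 60,
                                alpha = 0.1, seed = 33)
  calls <- call_qtl(scan, thr)
  expect_gte(nrow(calls$loci), 1)
  expect_equal(calls$loci$chromosome[1], 2)
  expect_match(calls$loci$name[1], "^Mc2\\.")
  expect_true(all(calls$loci$ci_lo_cM <= calls$loci$peak_cM &
                    calls$loci$peak_cM <= calls$loci$ci_hi_cM))
  ## every pointwise attachment really clears the pointwise cutoff
  pw <- calls$effects[calls$effects$level == "pointwise", , drop = FALSE]
  if (nrow(pw) > 0) {
    expect_true(all(pw$mLOD_pw | pw$aLOD_pw | pw$dLOD_pw | pw$iLOD_pw))
  }
  ## monotonicity: inflating every threshold never adds loci
  thr_hi <- thr
  thr_hi$genomewide <- lapply(thr$genomewide, function(v) v * 1.5)
  calls_hi <- call_qtl(scan, thr_hi)
  expect_lte(nrow(calls_hi$loci), nrow(calls$loci))
  ## variance decomposition of the call is positive for the real effect
  vd <- variance_decomposition(calls, adj)
  expect_gt(vd$R2_a[vd$trait == "t"], 0)
})

test_that("an empty or all-null scan yields no QTL", {
  np <- null_pipeline(5)
  scan <- genome_scan(np$adj, np$cr$geno, np$cr$map)
  thr <- list(genomewide = list(t = c(mLOD = 99, aLOD = 99, dLOD = 99,
                                      iLOD = 99)),
              alpha = 0.05, n_perm = 100, pointwise_lod = 1.3, seed = 1)
  class(thr) <- "threshold_set"
  calls <- call_qtl(scan, thr)
  expect_equal(nrow(calls$loci), 0)
  expect_equal(nrow(call_qtl(scan[0, ], thr)$loci), 0)
})

test_that("support intervals bracket the peak and nest with drop", {
  ## synthetic unimodal profile on one chromosome
  mkscan <- function(lods) {
    data.frame(trait = "t", marker_id = sprintf("m%d", seq_along(lods)),
               chromosome = 1, position_cM = 5 * (seq_along(lods) - 1),
               mLOD = lods, aLOD = 0, dLOD = 0, iLOD = 0,
               status = "ok", stringsAsFactors = FALSE)
  }
  prof <- mkscan(c(0.2, 1.1, 2.4, 3.6, 2.9, 1.0, 0.3))
  ## peak m4 at 15 cM (LOD 3.6); within 1 LOD: m4 and m5 only (2.4 < 2.6)
  ci1 <- support_interval(prof, "t", "m4", "mLOD", drop = 1)
  expect_true(ci1[1] <= 15 && 15 <= ci1[2])
  expect_equal(ci1, c(15, 20))
  ci15 <- support_interval(prof, "t", "m4", "mLOD", drop = 1.5)
  expect_equal(ci15, c(10, 20))
  ## drop = 0 degenerates to the peak (ties included)
  ci0 <- support_interval(prof, "t", "m4", "mLOD", drop = 0)
  expect_equal(ci0, c(15, 15))
  ## nestedness on random profiles
  set.seed(41)
  for (k in 1:20) {
    lods <- stats::runif(9, 0, 5)
    pk <- sprintf("m%d", which.max(lods))
    a <- support_interval(mkscan(lods), "t", pk, "mLOD", drop = 1)
    b <- support_interval(mkscan(lods), "t", pk, "mLOD", drop = 2)
    expect_true(b[1] <= a[1] && a[2] <= b[2])
  }
})

test_that("locus names follow the mouse-chromosome scheme", {
  loci <- data.frame(chromosome = c(12, 12, 19),
                     peak_cM = c(43.9, 9.7, 23.5))
  named <- name_qtl(loci)
  expect_equal(named$name, c("Mc12.1", "Mc12.2", "Mc19.1"))
  expect_equal(named$peak_cM, c(9.7, 43.9, 23.5))
  empty <- name_qtl(data.frame(chromosome = integer(0),
                               peak_cM = numeric(0)))
  expect_equal(nrow(empty), 0)
})

test_that("grouping replay on the published effect table finds nine loci", {
  fix <- load_qtl_table()
  flagged <- data.frame(trait = fix$trait, chromosome = fix$chromosome,
                        pos_cM = fix$pos_cM, mLOD_sig = fix$mLOD_sig,
                        aLOD_sig = fix$aLOD_sig, dLOD_sig = fix$dLOD_sig,
                        iLOD_sig = fix$iLOD_sig)
  loci <- qtl_from_flags(flagged, merge_window = 20)
  expect_equal(nrow(loci), 9)
  expect_equal(sum(loci$n_traits == 1), 4)
  ## chromosome 12 splits into two loci 34 cM apart
  expect_equal(sum(loci$chromosome == 12), 2)
  expect_equal(loci$name[loci$chromosome == 12], c("Mc12.1", "Mc12.2"))
})
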