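test_that("default pedigree reproduces the cross design sizes", {
  ped <- simulate_pedigree(seed = 1)
  expect_equal(sum(ped$generation == "F2"), 94)
  expect_equal(sum(ped$generation == "F3"), 345)
  expect_equal(sum(ped$analyzable & ped$generation == "F3"), 331)
  expect_true(validate_pedigree(ped))
  ## both cross directions represented among phenotyped generations
  sub <- ped[ped$generation %in% c("F2", "F3"), ]
  expect_setequal(unique(sub$grandmaternal_line), c("A", "B"))
})

test_that("empty-descendant config yields only founders and F1", {
  ped <- simulate_pedigree(cross_config(n_f2 = 0, n_f3 = 0,
                                        n_f3_analyzable = 0), seed = 1)
  expect_setequal(unique(ped$generation), c("F0", "F1"))
})

test_that("F2 cannot be produced without F1 of both sexes", {
  cfg <- cross_config(n_f2 = 10, n_f3 = 0, n_f3_analyzable = 0,
                      n_f1_per_cross = 1)  # alternating sex: males only
  expect_error(simulate_pedigree(cfg, seed = 1), "no F1 of one sex")
})

test_that("founders and F1 have the forced ordered genotypes", {
  cr <- small_cross(seed = 3)
  f0A <- cr$ped$id[cr$ped$generation == "F0" &
                     cr$ped$founder_line == "A" & !is.na(cr$ped$founder_line)]
  f0B <- cr$ped$id[cr$ped$generation == "F0" &
                     cr$ped$founder_line == "B" & !is.na(cr$ped$founder_line)]
  expect_true(all(cr$geno[f0A, ] == "AA"))
  expect_true(all(cr$geno[f0B, ] == "BB"))
  ## F1 are heterozygous everywhere with paternal allele = sire's line
  for (id in cr$ped$id[cr$ped$generation == "F1"]) {
    sire_line <- cr$ped$founder_line[cr$ped$id ==
                                       cr$ped$sire[cr$ped$id == id]]
    want <- if (sire_line == "A") "AB" else "BA"
    expect_true(all(cr$geno[id, ] == want))
  }
})

test_that("simulated transmission is Mendelian-consistent", {
  cr <- small_cross(seed = 5)
  geno <- cr$geno
  for (r in which(cr$ped$generation != "F0")) {
    id <- cr$ped$id[r]
    pat <- substr(geno[id, ], 1, 1)
    mat <- substr(geno[id, ], 2, 2)
    sire_alleles <- rbind(substr(geno[cr$ped$sire[r], ], 1, 1),
                          substr(geno[cr$ped$sire[r], ], 2, 2))
    dam_alleles <- rbind(substr(geno[cr$ped$dam[r], ], 1, 1),
                         substr(geno[cr$ped$dam[r], ], 2, 2))
    expect_true(all(pat == sire_alleles[1, ] | pat == sire_alleles[2, ]))
    expect_true(all(mat == dam_alleles[1, ] | mat == dam_alleles[2, ]))
  }
})

test_that("gamete recombination fraction matches the Haldane closed form", {
  ## two markers 10 cM apart: r = (1 - exp(-0.2))/2 = 0.09063
  map <- locus_map(chromosome = 1, n = 2, spacing = 10)
  n_gam <- 10000
  set.seed(42)
  pat <- c("A", "A")
  mat <- c("B", "B")
  rfrac <- haldane_r(c(10, 0))
  rec <- 0
  for (g in seq_len(n_gam)) {
    gam <- poeqtl:::sim_gamete(pat, mat, map$chromosome, rfrac)
    if (gam[1] != gam[2]) rec <- rec + 1
  }
  r_true <- haldane_r(10)
  expect_equal(r_true, 0.09063462, tolerance = 1e-6)
  ## binomial sampling band: 3.5 sd
  band <- 3.5 * sqrt(r_true * (1 - r_true) / n_gam)
  expect_lt(abs(rec / n_gam - r_true), band)
})

test_that("genotype class frequencies in a large F3 are near 1/4", {
  cfg <- cross_config(n_f3 = 2000, n_f3_analyzable = 2000)
  ped <- simulate_pedigree(cfg, seed = 8)
  map <- locus_map(n = 2)
  geno <- simulate_genotypes(ped, map, seed = 8)
  f3 <- ped$id[ped$generation == "F3"]
  freq <- table(geno[f3, 1]) / length(f3)
  expect_length(freq, 4)
  expect_true(all(freq > 0.15 & freq < 0.35))
})

test_that("noiseless phenotypes are exact functions of the genotype", {
  cr <- small_cross(seed = 2)
  ## all effects zero -> constant at the grand mean
  sp0 <- list(trait_spec("flat", grand_mean = 7, residual_sd = 0))
  ph0 <- simulate_phenotypes(cr$ped, cr$geno, cr$map, sp0, seed = 1)
  expect_true(all(ph0$flat == 7))
  ## single imprinted QTL i = 2: AB minus BA class means differ by 4
  spi <- trait_spec("imp", grand_mean = 0,
                    qtls = list(list(chromosome = 1, position_cM = 0,
                                     a = 0, d = 0, i = 2)),
                    residual_sd = 0)
  phi <- simulate_phenotypes(cr$ped, cr$geno, cr$map, list(spi), seed = 1)
  g <- cr$geno[phi$id, cr$map$marker_id[1]]
  expect_equal(mean(phi$imp[g == "AB"]) - mean(phi$imp[g == "BA"]), 4)
  expect_equal(mean(phi$imp[g == "AA"]), mean(phi$imp[g == "BB"]))
})

test_that("phenotypic variance matches the analytic component sum", {
  ## large F3 so sampling error is small; oracle = analytic variance
  ## given the realised genotype-class frequencies
  cfg <- cross_config(n_f3 = 5000, n_f3_analyzable = 5000)
  ped <- simulate_pedigree(cfg, seed = 9)
  map <- locus_map(n = 2)
  sp <- trait_spec("t", grand_mean = 0,
                   qtls = list(list(chromosome = 12, position_cM = 0,
                                    a = 1, d = 0.5, i = 0.8)),
                   family_sd = 0.5, residual_sd = 1)
  geno <- simulate_genotypes(ped, map, seed = 9)
  ph <- simulate_phenotypes(ped, geno, map, list(sp), seed = 9)
  f3 <- ph$id %in% ped$id[ped$generation == "F3"]
  y <- ph$t[f3]
  g <- geno[ph$id[f3], map$marker_id[1]]
  vals <- c(AA = 1, AB = 0.5 + 0.8, BA = 0.5 - 0.8, BB = -1)
  gv <- vals[g]
  v_analytic <- mean((gv - mean(gv))^2) + 0.5^2 + 1^2
  expect_lt(abs(stats::var(y) - v_analytic) / v_analytic, 0.05)
})

test_that("a trait referencing a missing chromosome errors", {
  cr <- small_cross(seed = 2)
  sp <- list(trait_spec("bad", qtls = list(list(chromosome = 9,
                                                position_cM = 0,
                                                a = 1, d = 0, i = 0))))
  expect_error(simulate_phenotypes(cr$ped, cr$geno, cr$map, sp, seed = 1),
               "not on the map")
})

test_that("unorder collapses reciprocal heterozygotes", {
  m <- matrix(c("AB", "BA", "AA", "BB"), 2, 2,
              dimnames = list(c("i1", "i2"), c("m1", "m2")))
  u <- unorder(m)
  expect_equal(u["i1", "m1"], "H")
  expect_equal(u["i2", "m1"], "H")
  expect_equal(u["i1", "m2"], "A")
  expect_equal(u["i2", "m2"], "B")
})

test_that("simulation is bit-identical under a fixed seed", {
  a <- small_cross(seed = 77)
  b <- small_cross(seed = 77)
  expect_identical(a$ped, b$ped)
  expect_identical(a$geno, b$geno)
  spa <- list(trait_spec("t", 1, family_sd = 0.3, residual_sd = 1))
  pa <- simulate_phenotypes(a$ped, a$geno, a$map, spa, seed = 5)
  pb <- simulate_phenotypes(b$ped, b$geno, b$map, spa, seed = 5)
  expect_identical(pa, pb)
})

test_that("all table writers round-trip through disk", {
  cr <- small_cross(seed = 4, n_f2 = 10, n_f3 = 20)
  td <- withr::local_tempdir()

  f <- file.path(td, "map.tsv")
  write_map_tsv(cr$map, f)
  expect_equal(read_map_tsv(f), cr$map)

  f <- file.path(td, "ped.tsv")
  write_pedigree_tsv(cr$ped, f)
  ped2 <- read_pedigree_tsv(f)
  expect_equal(as.data.frame(ped2), as.data.frame(cr$ped))

  f <- file.path(td, "geno.csv")
  write_genotypes_csv(cr$geno, f)
  expect_equal(unclass(read_genotypes_csv(f)), unclass(cr$geno),
               ignore_attr = "class")

  un <- unorder(cr$geno)
  f <- file.path(td, "ugeno.csv")
  write_genotypes_csv(un, f)
  expect_equal(unclass(read_genotypes_csv(f, ordered = FALSE)), un)

  sp <- list(trait_spec("weight", 30, family_sd = 1, residual_sd = 2))
  ph <- simulate_phenotypes(cr$ped, cr$geno, cr$map, sp, seed = 3)
  f <- file.path(td, "pheno.csv")
  write_phenotypes_csv(ph, f)
  ph2 <- read_phenotypes_csv(f)
  expect_equal(ph2$id, ph$id)
  expect_equal(ph2$weight, ph$weight, tolerance = 1e-12)
})

test_that("YAML simulation configs load into typed objects", {
  td <- withr::local_tempdir()
  f <- file.path(td, "cfg.yaml")
  writeLines(c(
    "sizes:", "  n_f2: 20", "  n_f3: 40", "  n_f3_analyzable: 38",
    "seed: 11",
    "traits:",
    "  - trait_name: bw", "    grand_mean: 30", "    residual_sd: 2"),
    f)
  cfg <- read_sim_config(f)
  expect_s3_class(cfg$config, "cross_config")
  expect_equal(cfg$config$n_f2, 20L)
  expect_equal(cfg$seed, 11)
  expect_equal(cfg$specs$bw$grand_mean, 30)
})
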