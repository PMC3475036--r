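# shared fixtures: everything is generated in code at test time

# compact map: n_chr chromosomes, spacing cM apart
small_map <- function(n_markers = 8L, n_chr = 2L, spacing = 10) {
  default_genetic_map(n_markers = n_markers, n_chromosomes = n_chr,
                      spacing_cM = spacing)
}

# one-chromosome map for single-locus work
locus_map <- function(chromosome = 12L, n = 3L, spacing = 10) {
  genetic_map(data.frame(
    marker_id = sprintf("c%d_m%d", chromosome, seq_len(n)),
    chromosome = chromosome,
    position_cM = spacing * (seq_len(n) - 1L),
    position_Mb = 2 * spacing * (seq_len(n) - 1L)))
}

# small cross for fast pipeline tests
small_cross <- function(seed = 1L, n_f2 = 40L, n_f3 = 120L,
                        map = small_map()) {
  cfg <- cross_config(n_f2 = n_f2, n_f3 = n_f3, n_f3_analyzable = n_f3)
  ped <- simulate_pedigree(cfg, seed = seed)
  geno <- simulate_genotypes(ped, map, seed = seed)
  list(ped = ped, map = map, geno = geno)
}

# balanced four-class design: k individuals per ordered class
balanced_classes <- function(k = 25L) {
  rep(c("AA", "AB", "BA", "BB"), each = k)
}

# OLS log10 likelihood-ratio LOD, the brute-force single-family oracle
ols_lod <- function(y, X_full, X_red) {
  rss <- function(X) sum(stats::lm.fit(X, y)$residuals^2)
  (length(y) / 2) * log10(rss(X_red) / rss(X_full))
}
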