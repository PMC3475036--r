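#' Haldane recombination fraction
#'
#' Converts a map distance in centimorgans to a recombination fraction
#' under the Haldane (no-interference) map function,
#' r = (1 - exp(-2d/100)) / 2.
#'
#' @param d_cM map distance in cM (vectorised).
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

## ordered genotype codes: paternal allele first
ORDERED_CODES <- c("AA", "AB", "BA", "BB")

## draw one gamete from a parent's (paternal, maternal) haplotypes:
## crossovers fall independently between adjacent markers with the
## Haldane probability for the interval
sim_gamete <- function(pat, mat, chr, rfrac) {
  n <- length(pat)
  ## which parental haplotype is copied at each marker (1 = pat, 2 = mat)
  src <- integer(n)
  start <- 1L
  for (block in split(seq_len(n), chr)) {
    cur <- sample.int(2L, 1L)
    src[block[1L]] <- cur
    if (length(block) > 1L) {
      xo <- stats::runif(length(block) - 1L) < rfrac[block[-length(block)]]
      for (j in seq_along(xo)) {
        if (xo[j]) cur <- 3L - cur
        src[block[j + 1L]] <- cur
      }
    }
  }
  ifelse(src == 1L, pat, mat)
}

#' Simulate ordered genotypes by gamete dropping
#'
#' Drops gametes through the pedigree: each transmitted haplotype is a
#' recombinant of the parent's paternal and maternal haplotypes, with
#' crossover probability between adjacent markers given by the Haldane
#' map function applied to the marker interval, independently across
#' intervals and chromosomes. F0 founders are homozygous for their line
#' allele at every marker. The offspring entry at a marker is (allele
#' from the sire's gamete, allele from the dam's gamete), i.e. an
#' ordered genotype.
#'
#' @param ped a `pedigree` (topologically ordered).
#' @param map a `genetic_map`.
#' @param seed integer seed.
#' @return A character matrix (individuals x markers, dimnames set) of
#'   ordered codes "AA", "AB", "BA", "BB"; class `ordered_geno`.
#' @export
simulate_genotypes <- function(ped, map, seed = 1L) {
  set.seed(seed)
  n_mark <- nrow(map)
  chr <- map$chromosome
  ## within-chromosome interval recombination fractions; the entry for
  ## the last marker of a chromosome is unused
  d <- c(diff(map$position_cM), 0)
  d[c(diff(chr) != 0, TRUE)] <- 0
  rfrac <- haldane_r(d)

  pat_h <- mat_h <- matrix(NA_character_, nrow(ped), n_mark,
                           dimnames = list(ped$id, map$marker_id))
  pos <- seq_len(nrow(ped))
  names(pos) <- ped$id
  for (i in seq_len(nrow(ped))) {
    if (ped$generation[i] == "F0") {
      pat_h[i, ] <- mat_h[i, ] <- ped$founder_line[i]
    } else {
      si <- pos[ped$sire[i]]
      di <- pos[ped$dam[i]]
      if (anyNA(pat_h[si, ]) || anyNA(pat_h[di, ])) {
        stop("parent genotypes missing for ", ped$id[i])
      }
      pat_h[i, ] <- sim_gamete(pat_h[si, ], mat_h[si, ], chr, rfrac)
      mat_h[i, ] <- sim_gamete(pat_h[di, ], mat_h[di, ], chr, rfrac)
    }
  }
  geno <- matrix(paste0(pat_h, mat_h), nrow(ped), n_mark,
                 dimnames = list(ped$id, map$marker_id))
  class(geno) <- c("ordered_geno", class(geno))
  geno
}

#' Collapse ordered genotypes to unordered calls
#'
#' Discards parent-of-origin information: AB and BA both become the
#' heterozygote code "H"; AA and BB become "A" and "B".
#'
#' @param geno ordered genotype matrix (codes AA/AB/BA/BB, NA allowed).
#' @return Character matrix of unordered codes "A", "H", "B".
#' @export
unorder <- function(geno) {
  out <- matrix(
    c(AA = "A", AB = "H", BA = "H", BB = "B")[geno],
    nrow(geno), ncol(geno), dimnames = dimnames(geno))
  out
}

#' Read / write genotype matrices as CSV
#'
#' One row per individual (first column `id`), one column per marker.
#' Ordered dialect uses codes AA/AB/BA/BB; unordered uses A/H/B; missing
#' entries are written as NA.
#'
#' @param path file path.
#' @param ordered logical; which code dialect to validate against.
#' @return `read_genotypes_csv` returns a character matrix with
#'   individuals as rownames.
#' @export
read_genotypes_csv <- function(path, ordered = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""), check.names = FALSE)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "character"
  rownames(m) <- ids
  valid <- if (ordered) ORDERED_CODES else c("A", "H", "B")
  bad <- !is.na(m) & !(m %in% valid)
  if (any(bad)) stop("invalid genotype codes in ", path)
  if (ordered) class(m) <- c("ordered_geno", class(m))
  m
}

#' @rdname read_genotypes_csv
#' @param geno genotype matrix with individual rownames.
#' @export
write_genotypes_csv <- function(geno, path) {
  df <- data.frame(id = rownames(geno),
                   unclass(geno)[, , drop = FALSE],
                   stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
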