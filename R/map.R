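#' Construct a genetic map
#'
#' A genetic map is a data frame of markers ordered by chromosome and
#' centimorgan position. Positions must be strictly increasing within a
#' chromosome (in both cM and Mb) and marker ids unique.
#'
#' @param markers data frame with columns `marker_id`, `chromosome`
#'   (integer 1-19), `position_cM` and `position_Mb`.
#' @return The validated map with class `genetic_map`, sorted by
#'   chromosome then position.
#' @export
genetic_map <- function(markers) {
  required <- c("marker_id", "chromosome", "position_cM", "position_Mb")
  missing_cols <- setdiff(required, names(markers))
  if (length(missing_cols) > 0L) {
    stop("map is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  markers <- as.data.frame(markers)[required]
  markers$marker_id <- as.character(markers$marker_id)
  markers$chromosome <- as.integer(markers$chromosome)
  markers <- markers[order(markers$chromosome, markers$position_cM), ,
                     drop = FALSE]
  rownames(markers) <- NULL
  if (anyDuplicated(markers$marker_id)) {
    stop("duplicated marker_id in map")
  }
  if (any(markers$position_cM < 0) || any(markers$position_Mb < 0)) {
    stop("marker positions must be non-negative")
  }
  for (chr in unique(markers$chromosome)) {
    sub <- markers[markers$chromosome == chr, ]
    if (any(diff(sub$position_cM) <= 0) || any(diff(sub$position_Mb) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", chr)
    }
  }
  class(markers) <- c("genetic_map", "data.frame")
  markers
}

#' Default autosomal marker map
#'
#' Places `n_markers` markers on 19 mouse autosomes at regular spacing,
#' emulating a panel of informative markers spaced about 5 cM apart.
#' Nominal physical positions use 1 cM = 2 Mb. X and Y are excluded:
#' the imprinting contrast is defined for autosomes only.
#'
#' @param n_markers total markers to place (default 164).
#' @param n_chromosomes number of autosomes (default 19).
#' @param spacing_cM distance between adjacent markers (default 5 cM).
#' @return A `genetic_map`.
#' @export
default_genetic_map <- function(n_markers = 164L, n_chromosomes = 19L,
                                spacing_cM = 5) {
  n_markers <- as.integer(n_markers)
  n_chromosomes <- as.integer(n_chromosomes)
  if (n_markers < n_chromosomes) {
    stop("need at least one marker per chromosome")
  }
  base <- n_markers %/% n_chromosomes
  extra <- n_markers %% n_chromosomes
  per_chr <- rep(base, n_chromosomes) + c(rep(1L, extra),
                                          rep(0L, n_chromosomes - extra))
  rows <- lapply(seq_len(n_chromosomes), function(chr) {
    k <- per_chr[chr]
    cm <- spacing_cM * (seq_len(k) - 1L)
    data.frame(
      marker_id = sprintf("M%02d_%03d", chr, seq_len(k)),
      chromosome = chr,
      position_cM = cm,
      position_Mb = 2 * cm,
      stringsAsFactors = FALSE
    )
  })
  genetic_map(do.call(rbind, rows))
}

#' Read / write a map as tab-separated text
#'
#' Columns: marker_id, chromosome, position_cM, position_Mb, with a
#' header row.
#'
#' @param path file path.
#' @return `read_map_tsv` returns a `genetic_map`.
#' @export
read_map_tsv <- function(path) {
  genetic_map(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_map_tsv
#' @param map a `genetic_map`.
#' @export
write_map_tsv <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## nearest marker to a (chromosome, cM) query; error if chromosome absent
nearest_marker <- function(map, chromosome, position_cM) {
  sub <- map[map$chromosome == chromosome, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("chromosome ", chromosome, " is not on the map")
  }
  sub$marker_id[which.min(abs(sub$position_cM - position_cM))]
}
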