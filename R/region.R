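#' Pseudoautosomal region map
#'
#' Builds a region map holding the two pseudoautosomal intervals (PAR1 at
#' Xp22.33, PAR2 at Xq28) for a genome build. Coordinates are 1-based with
#' half-open intervals `[start, end)`. Shipped defaults are the standard
#' Ensembl PAR definitions:
#' * GRCh37: PAR1 X:60,001-2,699,520; PAR2 X:154,931,044-155,260,560
#' * GRCh38: PAR1 X:10,001-2,781,479; PAR2 X:155,701,383-156,030,895
#' (closed published coordinates; `end` below is the exclusive bound).
#'
#' @param build One of `"GRCh37"`, `"GRCh38"`, `"custom"` (case
#'   insensitive; `"grch38"` and `"hg38"` style aliases accepted).
#' @param par1,par2 For `build = "custom"`, numeric length-2 vectors
#'   `c(start, end)` with `end` exclusive.
#' @return A list of class `region_map` with elements `build`, `par1`,
#'   `par2`.
#' @export
region_map <- function(build = "GRCh38", par1 = NULL, par2 = NULL) {
  key <- tolower(gsub("[^a-z0-9]", "", tolower(build)))
  if (key %in% c("grch37", "hg19", "37")) {
    par1 <- c(60001, 2699521)
    par2 <- c(154931044, 155260561)
    build <- "GRCh37"
  } else if (key %in% c("grch38", "hg38", "38")) {
    par1 <- c(10001, 2781480)
    par2 <- c(155701383, 156030896)
    build <- "GRCh38"
  } else if (key == "custom") {
    if (is.null(par1) || is.null(par2)) {
      stop("custom build requires par1 and par2 intervals", call. = FALSE)
    }
    build <- "custom"
  } else {
    stop("unknown build '", build,
         "'; accepted: GRCh37, GRCh38, custom", call. = FALSE)
  }
  stopifnot(length(par1) == 2, length(par2) == 2,
            par1[1] < par1[2], par2[1] < par2[2])
  if (max(par1[1], par2[1]) < min(par1[2], par2[2])) {
    stop("PAR intervals overlap", call. = FALSE)
  }
  structure(list(build = build, par1 = as.numeric(par1),
                 par2 = as.numeric(par2)),
            class = "region_map")
}

#' Normalize chromosome labels
#'
#' Strips a leading "chr" prefix and upper-cases sex chromosomes, so
#' `"chrX"`, `"x"` and `"X"` all map to `"X"`.
#'
#' @param chrom Character vector of chromosome labels.
#' @return Normalized labels.
#' @export
normalize_chrom <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  toupper(chrom)
}

#' Classify genomic region: PAR, non-PAR X, or autosome
#'
#' Every position gets exactly one label: `PAR1` or `PAR2` when it falls in
#' a configured pseudoautosomal interval on X, `NONPAR_X` elsewhere on X,
#' `AUTOSOME` off X. The Y chromosome and non-numeric labels other than X
#' are rejected, since sex-stratified autosomal and X counts are the only
#' meaningful inputs for the ratio.
#'
#' @param chrom Chromosome labels (normalized internally).
#' @param pos 1-based positions.
#' @param map A [region_map()].
#' @return Character vector with values in
#'   `c("PAR1", "PAR2", "NONPAR_X", "AUTOSOME")`.
#' @export
classify_region <- function(chrom, pos, map = region_map()) {
  stopifnot(inherits(map, "region_map"))
  chrom <- normalize_chrom(chrom)
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  if (any(!is.na(pos) & pos < 1)) stop("pos must be >= 1", call. = FALSE)
  ok <- chrom %in% c(as.character(1:22), "X", "MT", "M")
  if (any(!ok)) {
    stop("unknown chromosome label(s): ",
         paste(unique(chrom[!ok]), collapse = ", "),
         "; accepted: 1-22 (with or without 'chr' prefix), X, MT",
         call. = FALSE)
  }
  out <- rep("AUTOSOME", n)
  x <- chrom == "X"
  out[x] <- "NONPAR_X"
  out[x & pos >= map$par1[1] & pos < map$par1[2]] <- "PAR1"
  out[x & pos >= map$par2[1] & pos < map$par2[2]] <- "PAR2"
  out
}
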