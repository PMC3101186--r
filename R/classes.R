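#' @keywords internal
"_PACKAGE"

VALID_CHROMOSOMES <- c(as.character(1:22), "X")
GENOTYPE_CODES <- c("AA", "AB", "BB", "NC")

## synonyms accepted on input; canonical codes on the right
GENOTYPE_SYNONYMS <- c(
  AA = "AA", AB = "AB", BB = "BB", NC = "NC",
  BA = "AB", NoCall = "NC", NOCALL = "NC", NN = "NC", "--" = "NC", "." = "NC"
)

#' SNP annotation table
#'
#' Validates and normalizes a SNP annotation data frame with columns
#' `snp_id`, `chromosome`, `position_bp` and `array_label`.
#'
#' @param annotation data frame with the four mandatory columns.
#' @return The validated data frame (chromosome as character, position integer).
#' @export
snp_annotation <- function(annotation) {
  required <- c("snp_id", "chromosome", "position_bp", "array_label")
  missing_cols <- setdiff(required, names(annotation))
  if (length(missing_cols) > 0L) {
    stop("annotation is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  annotation$snp_id <- as.character(annotation$snp_id)
  annotation$chromosome <- as.character(annotation$chromosome)
  annotation$array_label <- as.character(annotation$array_label)
  annotation$position_bp <- as.integer(annotation$position_bp)
  dup <- annotation$snp_id[duplicated(annotation$snp_id)]
  if (length(dup) > 0L) {
    stop("duplicate snp_id in annotation: ", dup[1L])
  }
  bad_chr <- setdiff(unique(annotation$chromosome), VALID_CHROMOSOMES)
  if (length(bad_chr) > 0L) {
    stop("invalid chromosome label(s): ", paste(bad_chr, collapse = ", "))
  }
  if (anyNA(annotation$position_bp) || any(annotation$position_bp < 1L)) {
    bad <- annotation$snp_id[is.na(annotation$position_bp) | annotation$position_bp < 1L][1L]
    stop("position_bp must be an integer >= 1 (1-based); offending snp_id: ", bad)
  }
  rownames(annotation) <- NULL
  annotation[, required]
}

new_matrix_container <- function(cls, annotation, sample_ids, ...) {
  annotation <- snp_annotation(annotation)
  mats <- list(...)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (nrow(m) != nrow(annotation) || ncol(m) != length(sample_ids)) {
      stop(nm, " matrix dimensions do not match annotation/sample_ids")
    }
    dimnames(mats[[nm]]) <- list(annotation$snp_id, sample_ids)
  }
  structure(c(list(annotation = annotation, sample_ids = as.character(sample_ids)), mats),
            class = cls)
}

#' Genotype call matrix
#'
#' Container for per-(SNP, sample) genotype calls. Calls are stored as the
#' canonical codes `AA`, `AB`, `BB`, `NC`; common synonyms (`NoCall`, `NN`,
#' `--`, `BA`) are normalized on construction.
#'
#' @param calls character matrix (SNPs x samples) of genotype codes.
#' @param annotation SNP annotation (see [snp_annotation()]), one row per
#'   matrix row.
#' @param sample_ids character vector of column ids.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, annotation, sample_ids = colnames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(sample_ids)) stop("sample_ids required when calls has no colnames")
  mapped <- GENOTYPE_SYNONYMS[as.character(calls)]
  if (anyNA(mapped)) {
    bad <- which(is.na(mapped))[1L]
    rc <- arrayInd(bad, dim(calls))
    stop(sprintf("unknown genotype code '%s' at SNP row %d, sample column %d",
                 as.character(calls)[bad], rc[1L], rc[2L]))
  }
  calls <- matrix(unname(mapped), nrow = nrow(calls))
  new_matrix_container("genotype_matrix", annotation, sample_ids, calls = calls)
}

#' Allele-specific hybridization intensity matrix
#'
#' @param intensity_a,intensity_b nonnegative numeric matrices (SNPs x
#'   samples) for the A and B allele signals; `NA` marks a missing pair.
#' @param annotation SNP annotation.
#' @param sample_ids character vector of column ids.
#' @return An object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(intensity_a, intensity_b, annotation,
                             sample_ids = colnames(intensity_a)) {
  intensity_a <- as.matrix(intensity_a)
  intensity_b <- as.matrix(intensity_b)
  for (m in list(intensity_a, intensity_b)) {
    neg <- which(!is.na(m) & m < 0)
    if (length(neg) > 0L) {
      rc <- arrayInd(neg[1L], dim(m))
      stop(sprintf("negative intensity at SNP row %d, sample column %d", rc[1L], rc[2L]))
    }
  }
  new_matrix_container("intensity_matrix", annotation, sample_ids,
                       intensity_a = intensity_a, intensity_b = intensity_b)
}

#' Individual-level allele frequency matrix
#'
#' Holds per-(SNP, sample) individual-level allele frequencies lambda in
#' \[0, 1\]; `NA` marks missing cells.
#'
#' @param af numeric matrix (SNPs x samples) in \[0, 1\] or `NA`.
#' @param annotation SNP annotation.
#' @param sample_ids character vector of column ids.
#' @return An object of class `af_matrix`.
#' @export
af_matrix <- function(af, annotation, sample_ids = colnames(af)) {
  af <- as.matrix(af)
  bad <- which(!is.na(af) & (af < 0 | af > 1))
  if (length(bad) > 0L) {
    rc <- arrayInd(bad[1L], dim(af))
    stop(sprintf("allele frequency outside [0,1] at SNP row %d, sample column %d",
                 rc[1L], rc[2L]))
  }
  new_matrix_container("af_matrix", annotation, sample_ids, af = af)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d SNPs x %d samples (%d chromosome(s), arrays: %s)\n",
              nrow(x$annotation), length(x$sample_ids),
              length(unique(x$annotation$chromosome)),
              paste(unique(x$annotation$array_label), collapse = ", ")))
  invisible(x)
}

#' @export
print.af_matrix <- function(x, ...) {
  cat(sprintf("af_matrix: %d SNPs x %d samples, %.1f%% missing\n",
              nrow(x$af), ncol(x$af), 100 * mean(is.na(x$af))))
  invisible(x)
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d SNPs x %d samples\n",
              nrow(x$intensity_a), ncol(x$intensity_a)))
  invisible(x)
}

check_alignment <- function(a, b, what_a = "first", what_b = "second") {
  if (!identical(a$annotation$snp_id, b$annotation$snp_id)) {
    common <- intersect(a$annotation$snp_id, b$annotation$snp_id)
    if (length(common) == 0L) {
      stop("no overlapping SNPs between ", what_a, " and ", what_b, " inputs")
    }
    stop(what_a, " and ", what_b, " inputs must be aligned on the same SNPs ",
         "(subset/reorder before calling)")
  }
  if (!identical(a$sample_ids, b$sample_ids)) {
    common <- intersect(a$sample_ids, b$sample_ids)
    if (length(common) == 0L) {
      stop("no shared samples between ", what_a, " and ", what_b, " inputs")
    }
    stop(what_a, " and ", what_b, " inputs must have identical sample columns")
  }
  invisible(TRUE)
}
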