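## All artifacts are tab-separated UTF-8 text with one header line; missing
## values are written as NA. Reference files carry "#key=value" metadata
## lines before the header.

ANNOTATION_COLS <- c("snp_id", "chromosome", "position_bp", "array_label")

read_tsv_meta <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_idx <- grep("^#", lines)
  meta_idx <- meta_idx[meta_idx == seq_along(meta_idx)]  # leading block only
  meta <- list()
  for (ln in lines[meta_idx]) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substring(kv, eq + 1)
  }
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = NA, na.strings = "NA")
  list(meta = meta, table = tab)
}

write_tsv_meta <- function(tab, path, meta = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("#%s=%s", k, meta[[k]]), con)
  }
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

check_annotation_header <- function(tab, path) {
  missing_cols <- setdiff(ANNOTATION_COLS, names(tab))
  if (length(missing_cols) > 0L) {
    stop("file '", path, "' lacks mandatory annotation column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read / write a genotype call matrix
#'
#' The file is a wide TSV: the mandatory annotation columns `snp_id`,
#' `chromosome`, `position_bp`, `array_label` come first, followed by one
#' column per sample holding genotype codes (`AA`/`AB`/`BB`/`NC`; common
#' synonyms such as `NoCall` are accepted and normalized).
#'
#' @param path file path.
#' @return [read_genotype_matrix()] returns a [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read_tsv_meta(path)$table
  check_annotation_header(tab, path)
  sample_cols <- setdiff(names(tab), ANNOTATION_COLS)
  if (length(sample_cols) == 0L) stop("file '", path, "' has no sample columns")
  calls <- as.matrix(tab[, sample_cols, drop = FALSE])
  genotype_matrix(calls, tab[, ANNOTATION_COLS], sample_ids = sample_cols)
}

#' @param x object to write.
#' @rdname read_genotype_matrix
#' @export
write_genotype_matrix <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  tab <- cbind(x$annotation, as.data.frame(x$calls, check.names = FALSE))
  write_tsv_meta(tab, path)
}

#' Read / write an allele-intensity matrix
#'
#' Long-format TSV with columns `snp_id`, `chromosome`, `position_bp`,
#' `array_label`, `sample_id`, `intensity_a`, `intensity_b`; one row per
#' (SNP, sample) pair. Absent pairs become missing cells.
#'
#' @param path file path.
#' @return [read_intensity_matrix()] returns an [intensity_matrix()].
#' @export
read_intensity_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read_tsv_meta(path)$table
  check_annotation_header(tab, path)
  need <- c("sample_id", "intensity_a", "intensity_b")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop("file '", path, "' lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  neg <- which(tab$intensity_a < 0 | tab$intensity_b < 0)
  if (length(neg) > 0L) {
    stop(sprintf("negative intensity for snp_id '%s', sample '%s'",
                 tab$snp_id[neg[1L]], tab$sample_id[neg[1L]]))
  }
  annotation <- snp_annotation(unique(tab[, ANNOTATION_COLS]))
  sample_ids <- unique(as.character(tab$sample_id))
  ridx <- match(tab$snp_id, annotation$snp_id)
  cidx <- match(as.character(tab$sample_id), sample_ids)
  a <- matrix(NA_real_, nrow(annotation), length(sample_ids))
  b <- a
  a[cbind(ridx, cidx)] <- tab$intensity_a
  b[cbind(ridx, cidx)] <- tab$intensity_b
  intensity_matrix(a, b, annotation, sample_ids = sample_ids)
}

#' @param x object to write.
#' @rdname read_intensity_matrix
#' @export
write_intensity_matrix <- function(x, path) {
  stopifnot(inherits(x, "intensity_matrix"))
  n_snp <- nrow(x$intensity_a); n_smp <- length(x$sample_ids)
  keep <- !(is.na(x$intensity_a) & is.na(x$intensity_b))
  tab <- data.frame(
    x$annotation[rep(seq_len(n_snp), times = n_smp), , drop = FALSE],
    sample_id = rep(x$sample_ids, each = n_snp),
    intensity_a = as.vector(x$intensity_a),
    intensity_b = as.vector(x$intensity_b),
    check.names = FALSE
  )[as.vector(keep), ]
  write_tsv_meta(tab, path)
}

#' Read / write an individual-level allele frequency matrix
#'
#' Wide TSV with the annotation columns first and one numeric column in
#' \[0, 1\] (or `NA`) per sample.
#'
#' @param path file path.
#' @return [read_af_matrix()] returns an [af_matrix()].
#' @export
read_af_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read_tsv_meta(path)$table
  check_annotation_header(tab, path)
  sample_cols <- setdiff(names(tab), ANNOTATION_COLS)
  if (length(sample_cols) == 0L) stop("file '", path, "' has no sample columns")
  af <- as.matrix(tab[, sample_cols, drop = FALSE])
  storage.mode(af) <- "double"
  af_matrix(af, tab[, ANNOTATION_COLS], sample_ids = sample_cols)
}

#' @param x object to write.
#' @rdname read_af_matrix
#' @export
write_af_matrix <- function(x, path) {
  stopifnot(inherits(x, "af_matrix"))
  tab <- cbind(x$annotation, as.data.frame(x$af, check.names = FALSE))
  write_tsv_meta(tab, path)
}

#' Read / write a genotype-specific AF reference
#'
#' One row per (SNP, genotype class) with the per-class mean and standard
#' deviation of individual-level allele frequencies and the number of
#' samples behind them. Eligibility (`n >= min_count` and `sd > sd_floor`)
#' is recomputed from the metadata on read.
#'
#' @param path file path.
#' @return [read_af_reference()] returns an `af_reference` data frame.
#' @export
read_af_reference <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- read_tsv_meta(path)
  tab <- parsed$table
  need <- c("snp_id", "genotype", "mean", "sd", "n", ANNOTATION_COLS)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop("AF reference '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(!is.na(tab$sd) & tab$sd < 0)
  if (length(bad) > 0L) {
    stop(sprintf("negative sd for snp_id '%s', genotype %s",
                 tab$snp_id[bad[1L]], tab$genotype[bad[1L]]))
  }
  bad <- which(!is.na(tab$mean) & (tab$mean < 0 | tab$mean > 1))
  if (length(bad) > 0L) {
    stop(sprintf("mean outside [0,1] for snp_id '%s', genotype %s",
                 tab$snp_id[bad[1L]], tab$genotype[bad[1L]]))
  }
  meta <- parsed$meta
  new_af_reference(tab,
                   min_count = as.integer(meta$min_count %||% 3L),
                   sd_floor = as.numeric(meta$sd_floor %||% 1e-4),
                   population_label = meta$population_label %||% "unknown")
}

#' @param ref `af_reference` object to write.
#' @rdname read_af_reference
#' @export
write_af_reference <- function(ref, path) {
  stopifnot(inherits(ref, "af_reference"))
  tab <- as.data.frame(ref)
  tab$eligible <- NULL
  write_tsv_meta(tab, path, meta = list(
    population_label = attr(ref, "population_label"),
    min_count = attr(ref, "min_count"),
    sd_floor = format(attr(ref, "sd_floor"), digits = 17)
  ))
}

#' Read / write a CPA table
#'
#' Per-SNP coefficient of preferential amplification/hybridization:
#' columns `snp_id`, `kappa`, `n_het`, `fallback`.
#'
#' @param path file path.
#' @return [read_cpa_table()] returns a `cpa_table` data frame.
#' @export
read_cpa_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read_tsv_meta(path)$table
  need <- c("snp_id", "kappa", "n_het", "fallback")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop("CPA table '", path, "' lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(!(tab$kappa > 0))
  if (length(bad) > 0L) {
    stop("non-positive kappa for snp_id '", tab$snp_id[bad[1L]], "'")
  }
  tab$fallback <- as.logical(tab$fallback)
  structure(tab, class = c("cpa_table", "data.frame"))
}

#' @param x `cpa_table` to write.
#' @rdname read_cpa_table
#' @export
write_cpa_table <- function(x, path) {
  write_tsv_meta(as.data.frame(x), path)
}

#' Write an array-level quality index report
#'
#' TSV with metadata lines recording the index kind, summary statistic,
#' winsorization quantile and quantile convention.
#'
#' @param x `array_qi_table` data frame from [array_qi()].
#' @param path file path.
#' @export
write_array_qi <- function(x, path) {
  stopifnot(inherits(x, "array_qi_table"))
  write_tsv_meta(as.data.frame(x), path,
                 meta = list(quantile_rule = "type7_linear_interpolation"))
}

#' @rdname write_array_qi
#' @export
read_array_qi <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read_tsv_meta(path)$table
  need <- c("sample_id", "array_label", "scope", "index_kind", "summary_kind",
            "rho", "qi_value", "n_snps_used")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop("QI table '", path, "' lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  structure(tab, class = c("array_qi_table", "data.frame"))
}

#' Write / read a quality-index reference (upper confidence limits)
#'
#' Long TSV with one row per (stratum, level): the empirical (or lognormal)
#' upper confidence limit, plus the stratum's QI mean and SD used for
#' heatmap level coloring.
#'
#' @param x `qi_reference` from [build_qi_reference()].
#' @param path file path.
#' @export
write_qi_reference <- function(x, path) {
  stopifnot(inherits(x, "qi_reference"))
  write_tsv_meta(as.data.frame(x), path,
                 meta = list(quantile_rule = "type7_linear_interpolation"))
}

#' @rdname write_qi_reference
#' @export
read_qi_reference <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read_tsv_meta(path)$table
  need <- c("population_label", "array_label", "scope", "index_kind",
            "summary_kind", "rho", "level", "limit", "source", "mu_qi",
            "sigma_qi", "n_arrays")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop("QI reference '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  structure(tab, class = c("qi_reference", "data.frame"))
}

#' Write a detection-rate curve
#'
#' TSV with columns `r`, `level`, `mean_rate`, `sd_rate`, `n_replications`
#' and metadata recording the simulation seed and design.
#'
#' @param x `detection_curve` from [detection_rate_experiment()].
#' @param path file path.
#' @export
write_detection_curve <- function(x, path) {
  stopifnot(inherits(x, "detection_curve"))
  cfg <- attr(x, "config")
  write_tsv_meta(as.data.frame(x), path, meta = list(
    seed = cfg$seed %||% "NA",
    n_arrays = cfg$n_arrays, n_snps = cfg$n_snps %||% "NA",
    rho = cfg$rho, index_kind = cfg$index_kind,
    summary_kind = cfg$summary_kind,
    quantile_rule = "type7_linear_interpolation"
  ))
}
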