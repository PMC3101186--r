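#' Plot device specification
#'
#' @param output_path file to write.
#' @param format `"png"` or `"pdf"`.
#' @param width,height device size in inches.
#' @param dpi resolution for png output (>= 72).
#' @return A `plot_spec` list.
#' @export
plot_spec <- function(output_path, format = c("png", "pdf"), width = 10,
                      height = 7, dpi = 150L) {
  format <- match.arg(format)
  stopifnot(dpi >= 72)
  structure(list(output_path = output_path, format = format, width = width,
                 height = height, dpi = as.integer(dpi)),
            class = "plot_spec")
}

open_device <- function(spec) {
  if (spec$format == "png") {
    grDevices::png(spec$output_path, width = spec$width, height = spec$height,
                   units = "in", res = spec$dpi)
  } else {
    grDevices::pdf(spec$output_path, width = spec$width, height = spec$height)
  }
}

#' Allele-frequency profile plot
#'
#' One panel per chromosome: individual-level allele frequencies of one
#' sample against physical position (Mb), with a smoothed AF density curve
#' (fixed-bandwidth kernel estimate, pink) along the right margin of each
#' panel. A good sample shows three tight bands near 1, 0.5 and 0; poor
#' quality widens or merges the bands. With `genotype_based = TRUE` the
#' genotype-implied frequencies (1/0.5/0) are drawn instead, which
#' requires `genotypes`. Optional centromere gaps are masked when a
#' `gap_table` (columns `chromosome`, `start_bp`, `end_bp`) is supplied.
#'
#' @param af [af_matrix()].
#' @param sample_id sample to draw.
#' @param spec [plot_spec()].
#' @param genotype_based logical; plot genotype-implied AFs.
#' @param genotypes [genotype_matrix()], needed when `genotype_based`.
#' @param gap_table optional centromere gap table.
#' @param density_bw kernel bandwidth of the marginal AF density (default
#'   0.02 on the AF scale).
#' @return The output path, invisibly.
#' @export
plot_af <- function(af, sample_id, spec, genotype_based = FALSE,
                    genotypes = NULL, gap_table = NULL, density_bw = 0.02) {
  stopifnot(inherits(af, "af_matrix"), inherits(spec, "plot_spec"))
  col_idx <- match(sample_id, af$sample_ids)
  if (is.na(col_idx)) stop("unknown sample: ", sample_id)
  vals <- if (genotype_based) {
    if (is.null(genotypes)) stop("genotype_based = TRUE requires 'genotypes'")
    check_alignment(af, genotypes, "AF", "genotype")
    genotype_implied_af(genotypes$calls[, col_idx])
  } else {
    af$af[, col_idx]
  }
  chrs <- unique(af$annotation$chromosome)
  chrs <- chrs[order(match(chrs, VALID_CHROMOSOMES))]
  open_device(spec)
  on.exit(grDevices::dev.off())
  nc <- ceiling(sqrt(length(chrs)))
  nr <- ceiling(length(chrs) / nc)
  graphics::par(mfrow = c(nr, nc), mar = c(3, 3, 2, 0.5), mgp = c(1.8, 0.6, 0))
  for (chr in chrs) {
    sel <- af$annotation$chromosome == chr
    pos <- af$annotation$position_bp[sel] / 1e6
    v <- vals[sel]
    if (!is.null(gap_table)) {
      g <- gap_table[gap_table$chromosome == chr, , drop = FALSE]
      for (i in seq_len(nrow(g))) {
        v[pos * 1e6 >= g$start_bp[i] & pos * 1e6 <= g$end_bp[i]] <- NA
      }
    }
    graphics::plot(pos, v, pch = 16, cex = 0.3, col = "grey30",
                   xlab = "position (Mb)", ylab = "AF", ylim = c(0, 1),
                   main = paste0("chr", chr))
    ok <- !is.na(v)
    if (sum(ok) >= 2L) {
      d <- stats::density(v[ok], bw = density_bw, from = 0, to = 1)
      xr <- range(pos, na.rm = TRUE)
      scale <- 0.15 * diff(xr) / max(d$y)
      graphics::lines(xr[2] - d$y * scale, d$x, col = "deeppink", lwd = 1.5)
    }
  }
  invisible(spec$output_path)
}

#' Quality-index heatmap
#'
#' Samples x array-labels grid of array-level quality indices. Colors
#' interpolate from dark green to white across the reference levels
#' `mu + k * sigma`, k = 0..6, where mu and sigma are the reference QI
#' mean and SD of each array stratum; values above `mu + 6 sigma` saturate
#' at white. Cells whose QI exceeds the upper confidence limit at `level`
#' carry a light-blue overlay frame.
#'
#' @param qi_table `array_qi_table` (GENOME-scope rows are drawn).
#' @param ref `qi_reference` providing `mu_qi`, `sigma_qi` and limits.
#' @param spec [plot_spec()].
#' @param level confidence level of the overlay (default 0.95).
#' @return The output path, invisibly.
#' @export
plot_qi_heatmap <- function(qi_table, ref, spec, level = 0.95) {
  stopifnot(inherits(qi_table, "array_qi_table"), inherits(ref, "qi_reference"),
            inherits(spec, "plot_spec"))
  rep_tab <- detect_poor_arrays(qi_table, ref, level = level)
  samples <- unique(rep_tab$sample_id)
  arrays <- unique(rep_tab$array_label)
  open_device(spec)
  on.exit(grDevices::dev.off())
  ramp <- grDevices::colorRampPalette(c("darkgreen", "white"))(7)
  graphics::par(mar = c(4, 6, 2, 8), xpd = NA)
  graphics::plot(NA, xlim = c(0.5, length(arrays) + 0.5),
                 ylim = c(0.5, length(samples) + 0.5), xlab = "", ylab = "",
                 axes = FALSE, main = "Quality index heatmap")
  graphics::axis(1, at = seq_along(arrays), labels = arrays, tick = FALSE)
  graphics::axis(2, at = seq_along(samples), labels = samples, las = 2,
                 tick = FALSE, cex.axis = 0.7)
  for (i in seq_len(nrow(rep_tab))) {
    x <- match(rep_tab$array_label[i], arrays)
    y <- match(rep_tab$sample_id[i], samples)
    st <- ref[ref$array_label == rep_tab$array_label[i] &
                ref$scope == "GENOME", , drop = FALSE]
    mu <- st$mu_qi[1L]; sg <- st$sigma_qi[1L]
    k <- if (is.na(mu) || is.na(sg) || sg <= 0) 6 else
      (rep_tab$qi_value[i] - mu) / sg
    bin <- min(max(floor(k), 0), 6) + 1L
    graphics::rect(x - 0.45, y - 0.45, x + 0.45, y + 0.45,
                   col = ramp[bin], border = "grey70")
    if (isTRUE(rep_tab$flag[i])) {
      graphics::rect(x - 0.45, y - 0.45, x + 0.45, y + 0.45,
                     col = grDevices::adjustcolor("lightblue", 0.45),
                     border = "steelblue", lwd = 2)
    }
  }
  lx <- length(arrays) + 1
  graphics::text(lx, length(samples), "QI level", adj = 0, cex = 0.8)
  for (k in 0:6) {
    graphics::rect(lx, length(samples) - 1 - k * 0.6, lx + 0.4,
                   length(samples) - 0.6 - k * 0.6, col = ramp[k + 1L],
                   border = "grey70")
    lab <- if (k == 0) "mu" else sprintf("mu + %dsigma", k)
    graphics::text(lx + 0.5, length(samples) - 0.8 - k * 0.6, lab, adj = 0,
                   cex = 0.7)
  }
  invisible(spec$output_path)
}

#' Per-chromosome quality-index polygon (radar) plot
#'
#' One closed polygon per sample with a vertex per chromosome at radius
#' equal to the chromosome-scope quality index, over a reference circle at
#' the upper confidence limit: vertices poking outside the circle mark
#' chromosomes whose index exceeds the limit.
#'
#' @param qi_table `array_qi_table` with chromosome-scope rows.
#' @param ref `qi_reference` supplying the limit (GENOME stratum of the
#'   sample's array label).
#' @param sample_id sample to draw.
#' @param spec [plot_spec()].
#' @param level confidence level of the reference circle (default 0.95).
#' @return The output path, invisibly.
#' @export
plot_qi_polygon <- function(qi_table, ref, sample_id, spec, level = 0.95) {
  stopifnot(inherits(qi_table, "array_qi_table"), inherits(spec, "plot_spec"))
  rows <- qi_table[qi_table$sample_id == sample_id &
                     qi_table$scope != "GENOME", , drop = FALSE]
  if (nrow(rows) < 3L) stop("need chromosome-scope QIs for at least 3 chromosomes")
  rows <- rows[order(match(rows$scope, VALID_CHROMOSOMES)), ]
  sel <- ref$array_label == rows$array_label[1L] & ref$scope == "GENOME" &
    abs(ref$level - level) < 1e-9
  if (!any(sel)) {
    stop("no reference stratum for array '", rows$array_label[1L],
         "' at level ", level)
  }
  limit <- ref$limit[which(sel)[1L]]
  theta <- 2 * pi * (seq_len(nrow(rows)) - 1) / nrow(rows)
  rmax <- max(rows$qi_value, limit) * 1.15
  open_device(spec)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(1, 1, 2, 1))
  graphics::plot(NA, xlim = c(-rmax, rmax), ylim = c(-rmax, rmax), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = paste("QI polygon:", sample_id))
  tt <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(limit * cos(tt), limit * sin(tt), col = "red", lty = 2)
  graphics::polygon(rows$qi_value * cos(theta), rows$qi_value * sin(theta),
                    border = "darkgreen", lwd = 2)
  graphics::text(rmax * cos(theta) * 0.97, rmax * sin(theta) * 0.97,
                 rows$scope, cex = 0.7)
  invisible(spec$output_path)
}

#' Genotype call rate plot
#'
#' Per-sample genome-scope GCR as a bar chart with a configurable
#' threshold line; the GCR axis is bounded to \[0, 1\].
#'
#' @param gcr `gcr_table` from [compute_gcr()].
#' @param spec [plot_spec()].
#' @param threshold horizontal reference line (default 0.95).
#' @return The output path, invisibly.
#' @export
plot_gcr <- function(gcr, spec, threshold = 0.95) {
  stopifnot(inherits(gcr, "gcr_table"), inherits(spec, "plot_spec"))
  rows <- gcr[gcr$scope == "GENOME", , drop = FALSE]
  open_device(spec)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(6, 4, 2, 1))
  graphics::barplot(rows$gcr, names.arg = rows$sample_id, las = 2,
                    ylim = c(0, 1), ylab = "genotype call rate",
                    col = ifelse(rows$gcr < threshold, "indianred", "seagreen"),
                    main = "Genotype call rate")
  graphics::abline(h = threshold, lty = 2, col = "red")
  invisible(spec$output_path)
}
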