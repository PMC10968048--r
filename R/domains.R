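#' Order cells by gauge expression
#'
#' Stable ascending sort of the cells by the normalised expression of the
#' gauge gene; ties keep the input order. The sorted gauge curve is the
#' differentiation axis every downstream step works on.
#'
#' @param nm a [norm_matrix()].
#' @param gauge_gene gauge symbol (must be present).
#' @return object of class `ordered_sample`: `matrix` (reordered
#'   [norm_matrix()]), `gauge_gene`, `gauge_values` (ascending),
#'   `order` (permutation applied).
#' @export
order_by_gauge <- function(nm, gauge_gene = "KRT12") {
  stopifnot(inherits(nm, "norm_matrix"))
  g <- gene_values(nm, gauge_gene)
  o <- order(g)  # stable: ties keep input order
  om <- norm_matrix(nm$values[, o, drop = FALSE],
                    gene_ids = nm$gene_ids,
                    cell_ids = nm$cell_ids[o],
                    probed_gene_count = nm$probed_gene_count,
                    sample_label = nm$sample_label[o])
  structure(list(matrix = om, gauge_gene = gauge_gene,
                 gauge_values = g[o], order = o),
            class = "ordered_sample")
}

#' @export
print.ordered_sample <- function(x, ...) {
  cat("ordered_sample:", length(x$gauge_values), "cells sorted by",
      x$gauge_gene, "; range", round(min(x$gauge_values), 2), "-",
      round(max(x$gauge_values), 2), "A.U.\n")
  invisible(x)
}

#' Amalgamate replicate samples
#'
#' Concatenates the cells of unit-MGC normalised replicate samples over the
#' intersection of their gene sets. No re-scaling is applied: the unit-MGC
#' normalisation is the cross-sample calibration. Sample labels are kept per
#' cell; duplicate barcodes are disambiguated by a sample index prefix.
#'
#' @param samples list of [norm_matrix()] objects (>= 2).
#' @return a single [norm_matrix()].
#' @export
amalgamate <- function(samples) {
  stopifnot(length(samples) >= 2L,
            all(vapply(samples, inherits, logical(1L), "norm_matrix")))
  genes <- Reduce(intersect, lapply(samples, `[[`, "gene_ids"))
  if (length(genes) == 0L) stop("empty gene intersection across samples")
  probed <- unique(vapply(samples, `[[`, integer(1L), "probed_gene_count"))
  if (length(probed) > 1L)
    warning("samples differ in probed_gene_count; using the first")
  vals <- do.call(cbind, lapply(samples, function(s)
    s$values[genes, , drop = FALSE]))
  ids <- unlist(lapply(samples, `[[`, "cell_ids"), use.names = FALSE)
  if (anyDuplicated(ids))
    ids <- unlist(lapply(seq_along(samples), function(i)
      paste0("s", i, ":", samples[[i]]$cell_ids)), use.names = FALSE)
  labels <- unlist(lapply(samples, `[[`, "sample_label"), use.names = FALSE)
  norm_matrix(vals, gene_ids = genes, cell_ids = ids,
              probed_gene_count = probed[1L], sample_label = labels)
}

# SSE of the best continuous piecewise-linear fit with breakpoints `b`
# (hinge positions on x = 1..n), slopes constrained non-negative and
# non-decreasing. Fast path: unconstrained least squares, accepted when the
# constraint is already satisfied; otherwise non-negative least squares on
# the slope-increment basis.
.pwl_sse <- function(x, y, b) {
  H <- if (length(b)) outer(x, b, function(xx, bb) pmax(xx - bb, 0)) else
    matrix(0, length(x), 0L)
  A <- cbind(1, x, H)
  fit <- stats::lm.fit(A, y)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  if (all(co[-1L] >= -1e-9)) return(sum(fit$residuals^2))
  A2 <- cbind(1, -1, x, H)
  sol <- pracma::lsqnonneg(A2, y)
  sum((y - A2 %*% sol$x)^2)
}

# Fitted values of the constrained piecewise-linear model at breakpoints b.
.pwl_fit <- function(x, y, b) {
  H <- if (length(b)) outer(x, b, function(xx, bb) pmax(xx - bb, 0)) else
    matrix(0, length(x), 0L)
  A2 <- cbind(1, -1, x, H)
  sol <- pracma::lsqnonneg(A2, y)$x
  co <- c(sol[1L] - sol[2L], sol[-(1:2)])
  list(fitted = as.vector(cbind(1, x, H) %*% co),
       intercept = co[1L], slope_increments = co[-1L],
       slopes = cumsum(co[-1L]))
}

# Coordinate-descent search for the SSE-minimising breakpoints of a
# k-breakpoint continuous piecewise-linear fit. Multi-resolution grid per
# coordinate; multistart from equal-rank and equal-value initialisations.
.fit_breakpoints <- function(y, nseg, min_seg = 5L, max_iter = 12L) {
  n <- length(y)
  k <- nseg - 1L
  x <- seq_len(n)
  if (k == 0L) return(list(breaks = integer(0), sse = .pwl_sse(x, y, integer(0))))
  starts <- list(round(seq_len(k) * n / nseg))
  # equal-value start: ranks where y first exceeds evenly spaced levels
  lv <- min(y) + (max(y) - min(y)) * seq_len(k) / nseg
  bv <- vapply(lv, function(l) which.max(y >= l), integer(1L))
  bv <- pmin(pmax(sort(bv), min_seg), n - min_seg)
  if (!any(duplicated(bv))) starts <- c(starts, list(bv))
  best <- NULL
  for (b0 in starts) {
    b <- pmin(pmax(b0, min_seg), n - min_seg)
    if (any(diff(b) < min_seg)) b <- round(seq_len(k) * n / nseg)
    sse <- .pwl_sse(x, y, b)
    for (iter in seq_len(max_iter)) {
      improved <- FALSE
      for (j in seq_len(k)) {
        lo <- if (j == 1L) min_seg else b[j - 1L] + min_seg
        hi <- if (j == k) n - min_seg else b[j + 1L] - min_seg
        if (hi <= lo) next
        stride <- max(1L, (hi - lo) %/% 40L)
        cand <- unique(c(seq(lo, hi, by = stride), hi))
        while (TRUE) {
          sses <- vapply(cand, function(cc) {
            bb <- b; bb[j] <- cc; .pwl_sse(x, y, bb)
          }, numeric(1L))
          ci <- which.min(sses)
          cbest <- cand[ci]
          if (stride == 1L) break
          stride2 <- max(1L, stride %/% 6L)
          cand <- seq(max(lo, cbest - stride), min(hi, cbest + stride),
                      by = stride2)
          stride <- stride2
        }
        if (sses[ci] + 1e-12 < sse) {
          sse <- sses[ci]; b[j] <- cbest; improved <- TRUE
        }
      }
      if (!improved) break
    }
    if (is.null(best) || sse < best$sse) best <- list(breaks = b, sse = sse)
  }
  best
}

# Hierarchical breakpoint search over the positive-gauge curve. The last
# domain's rise dwarfs the low-range structure (hundreds vs units of A.U.),
# so a joint SSE fit would spend its segments inside the final ramp. Like
# the graphical procedure the fit stands in for, the takeoff of the final
# ramp is located first (2-segment fit on the full curve), the earlier
# boundaries are then fitted on the zoomed-in low range, and a final local
# joint refinement (stride-1 coordinate descent within +/-10 ranks) polishes
# all breakpoints.
.segment_positive <- function(y, k_pos, min_seg) {
  m <- length(y)
  x <- seq_len(m)
  if (k_pos == 1L) return(integer(0))
  take <- .fit_breakpoints(y, nseg = 2L, min_seg = min_seg)
  t0 <- take$breaks[1L]
  br <- if (k_pos == 2L) t0 else {
    lowr <- .fit_breakpoints(y[seq_len(t0)], nseg = k_pos - 1L,
                             min_seg = min_seg)
    c(lowr$breaks, t0)
  }
  br <- sort(br)
  # local joint refinement, last boundary first (the takeoff correction
  # matters most), iterated until stable
  sse <- .pwl_sse(x, y, br)
  for (pass in seq_len(6L)) {
    moved <- FALSE
    for (j in rev(seq_along(br))) {
      lo <- max(if (j == 1L) min_seg else br[j - 1L] + min_seg, br[j] - 10L)
      hi <- min(if (j == length(br)) m - min_seg else br[j + 1L] - min_seg,
                br[j] + 10L)
      if (hi <= lo) next
      cand <- seq.int(lo, hi)
      sses <- vapply(cand, function(cc) {
        bb <- br; bb[j] <- cc; .pwl_sse(x, y, bb)
      }, numeric(1L))
      if (min(sses) + 1e-12 < sse) {
        br[j] <- cand[which.min(sses)]
        sse <- min(sses)
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  br
}

#' Segment the sorted gauge curve into expression domains
#'
#' The first domain (D0) is forced to be exactly the gauge-negative cells.
#' The remaining boundaries are fitted by continuous piecewise-linear least
#' squares on (cell rank, gauge value), with segment slopes constrained
#' non-negative and non-decreasing — a reproducible stand-in for reading the
#' inflections off the plotted curve. In manual mode the supplied domain end
#' indices are validated (boundaries never split a tie block of equal gauge
#' values; offending boundaries are snapped to the block end) and used as is.
#'
#' @param os an [order_by_gauge()] result.
#' @param n_domains number of domains including D0 (default 5: D0-D4).
#' @param mode `"auto"` (fit) or `"manual"` (use `manual_boundaries`).
#' @param manual_boundaries integer vector of domain end indices (cumulative,
#'   last equal to the number of cells), length `n_domains`.
#' @param min_seg minimum cells per fitted segment.
#' @param d4i_size size of the initial-D4 subdomain (default 2000 cells).
#' @return object of class `domain_partition`: `boundaries` (named end
#'   indices), `sizes`, `table` (domain, start/end index, gauge range,
#'   n_cells), `d4i_size`, `fit` (auto mode diagnostics).
#' @export
segment_domains <- function(os, n_domains = 5L, mode = c("auto", "manual"),
                            manual_boundaries = NULL, min_seg = 5L,
                            d4i_size = 2000L) {
  mode <- match.arg(mode)
  stopifnot(inherits(os, "ordered_sample"), n_domains >= 2L)
  g <- os$gauge_values
  n <- length(g)
  nz <- sum(g == 0)
  dnames <- paste0("D", seq_len(n_domains) - 1L)
  fit_info <- NULL
  if (mode == "manual") {
    if (is.null(manual_boundaries) || length(manual_boundaries) != n_domains)
      stop("manual mode requires ", n_domains, " domain end indices")
    b <- as.integer(manual_boundaries)
    if (b[n_domains] != n)
      stop("last manual boundary must equal the number of cells (", n, ")")
    # snap boundaries that split a tie block of equal gauge values
    for (i in seq_len(n_domains - 1L)) {
      while (b[i] < n && g[b[i]] == g[b[i] + 1L]) b[i] <- b[i] + 1L
    }
    if (any(diff(b) <= 0) || b[1L] < 0)
      stop("manual boundaries must be strictly increasing after tie snapping")
    bounds <- b
  } else {
    k_pos <- n_domains - 1L  # segments among positive-gauge cells
    m <- n - nz
    if (m < k_pos * min_seg)
      stop("fewer positive-gauge cells (", m, ") than needed for ",
           k_pos, " segments")
    y <- g[(nz + 1L):n]
    br <- .segment_positive(y, k_pos, min_seg)
    bounds <- as.integer(c(nz, nz + br, n))
    fit_info <- list(sse = .pwl_sse(seq_len(m), y, br), positive_breaks = br)
  }
  starts <- c(1L, utils::head(bounds, -1L) + 1L)
  sizes <- diff(c(0L, bounds))
  names(bounds) <- names(sizes) <- dnames
  rng <- t(vapply(seq_len(n_domains), function(i) {
    if (sizes[i] == 0L) return(c(NA_real_, NA_real_))
    range(g[starts[i]:bounds[i]])
  }, numeric(2L)))
  tab <- data.frame(domain = dnames, start_index = starts,
                    end_index = unname(bounds), gauge_min = rng[, 1L],
                    gauge_max = rng[, 2L], n_cells = unname(sizes),
                    stringsAsFactors = FALSE)
  last <- n_domains
  d4n <- sizes[last]
  structure(list(boundaries = bounds, sizes = sizes, table = tab,
                 n_cells = n, n_zero = nz,
                 d4i_size = min(d4i_size, d4n),
                 d4ex_size = max(0L, d4n - d4i_size),
                 gauge_gene = os$gauge_gene, mode = mode, fit = fit_info),
            class = "domain_partition")
}

#' @export
print.domain_partition <- function(x, ...) {
  cat("domain_partition (", x$mode, " mode):\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Build the trimmed comparison groups
#'
#' Converts a [domain_partition()] into the named cell-index sets used in
#' the differential comparisons: the raw domains, the D23 and D123 unions
#' (untrimmed), and the two 1000-cell windows at the start of D4 (after a
#' 100-cell post-D3 gap). For the D1-D2 and D2-D3 comparisons only, each
#' domain loses `interface_trim` cells at the shared interface to avoid the
#' intermingling zone.
#'
#' @param dp a [domain_partition()] (5 domains).
#' @param interface_trim cells removed on each side of the D1/D2 and D2/D3
#'   interfaces (those comparisons only).
#' @param post_d3_gap cells skipped at the start of D4.
#' @param window cells per D4 window.
#' @return object of class `comparison_groups`: named index vectors in
#'   `groups`, comparison-ready pairs in `pairs`, and a replayable
#'   `trim_log`.
#' @export
build_comparison_groups <- function(dp, interface_trim = 10L,
                                    post_d3_gap = 100L, window = 1000L) {
  stopifnot(inherits(dp, "domain_partition"), length(dp$sizes) == 5L)
  b <- dp$boundaries
  idx <- function(d) {
    i <- match(d, names(b))
    lo <- if (i == 1L) 1L else b[i - 1L] + 1L
    if (b[i] < lo) return(integer(0))
    seq.int(lo, b[i])
  }
  need <- post_d3_gap + 2L * window
  if (dp$sizes["D4"] < need)
    stop("D4 has ", dp$sizes["D4"], " cells; at least ", need,
         " required for the post-D3 gap plus two windows")
  D0 <- idx("D0"); D1 <- idx("D1"); D2 <- idx("D2"); D3 <- idx("D3")
  D4 <- idx("D4")
  D4i1 <- D4[(post_d3_gap + 1L):(post_d3_gap + window)]
  D4i2 <- D4[(post_d3_gap + window + 1L):(post_d3_gap + 2L * window)]
  tr <- function(v, head = 0L, tail = 0L) {
    if (length(v) <= head + tail) stop("interface trim removes a whole domain")
    v[seq.int(head + 1L, length(v) - tail)]
  }
  groups <- list(D0 = D0, D1 = D1, D2 = D2, D3 = D3,
                 D23 = c(D2, D3), D123 = c(D1, D2, D3),
                 D4i.1 = D4i1, D4i.2 = D4i2)
  pairs <- list(
    "D0-D1" = list(A = D0, B = D1),
    "D1-D2" = list(A = tr(D1, tail = interface_trim),
                   B = tr(D2, head = interface_trim)),
    "D2-D3" = list(A = tr(D2, tail = interface_trim),
                   B = tr(D3, head = interface_trim)),
    "D1-D23" = list(A = D1, B = c(D2, D3)),
    "D0-D123" = list(A = D0, B = c(D1, D2, D3)),
    "D123-D4i.1" = list(A = c(D1, D2, D3), B = D4i1),
    "D4i.1-D4i.2" = list(A = D4i1, B = D4i2))
  trim_log <- data.frame(
    rule = c("D1-D2:A_tail", "D1-D2:B_head", "D2-D3:A_tail", "D2-D3:B_head",
             "D4:post_d3_gap", "D4:beyond_windows"),
    n_removed = c(interface_trim, interface_trim, interface_trim,
                  interface_trim, post_d3_gap,
                  length(D4) - post_d3_gap - 2L * window),
    stringsAsFactors = FALSE)
  structure(list(groups = groups, pairs = pairs, trim_log = trim_log,
                 params = list(interface_trim = interface_trim,
                               post_d3_gap = post_d3_gap, window = window)),
            class = "comparison_groups")
}

#' Split a gauge-ordered sample into quantile bins
#'
#' Divides the first `n_cells` of the ordered sample into `n_bins` equal
#' consecutive bins (remainder cells dropped from the tail) and returns the
#' first and last bins, the Qstart/Qend groups of the central-cornea
#' analysis.
#'
#' @param os an [order_by_gauge()] result.
#' @param n_cells cells to use (default all).
#' @param n_bins number of bins (default 4, i.e. quartiles).
#' @return list with `Qstart`, `Qend` (index vectors), `bin_size`, `n_bins`,
#'   `dropped`.
#' @export
quartile_split <- function(os, n_cells = NULL, n_bins = 4L) {
  stopifnot(inherits(os, "ordered_sample"))
  total <- length(os$gauge_values)
  if (is.null(n_cells)) n_cells <- total
  if (n_cells > total) stop("n_cells exceeds available cells (", total, ")")
  if (n_bins > n_cells) stop("more bins than cells")
  sz <- n_cells %/% n_bins
  list(Qstart = seq_len(sz),
       Qend = seq.int((n_bins - 1L) * sz + 1L, n_bins * sz),
       bin_size = sz, n_bins = n_bins, dropped = n_cells - n_bins * sz)
}
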