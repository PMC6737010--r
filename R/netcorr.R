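# Network-wise average positive/negative correlations and system segregation.

# Cell masks for one network vs the partition. Returns logical matrices over
# the submatrix of partition nodes: within-network (upper-triangle unordered
# pairs expanded symmetric) and between-network (rows of k vs all others).
.net_cells <- function(C, P) {
  pos <- match(P$roi_id, C$node_ids)
  if (anyNA(pos)) stop("partition node missing from connectivity matrix")
  z <- conn_na_view(C)[pos, pos, drop = FALSE]
  list(z = z, network = P$network)
}

# Mean over unmasked cells of `z` selected by logical matrix `sel` and sign
# predicate. Uses unordered pairs: `sel` must be symmetric; the upper
# triangle is averaged. Returns c(mean, n) with mean NA when no cell.
.cell_mean <- function(z, sel, sign = c("pos", "neg")) {
  sign <- match.arg(sign)
  keep <- sel & upper.tri(sel) & !is.na(z)
  vals <- z[keep]
  vals <- if (sign == "pos") vals[vals > 0] else vals[vals < 0]
  if (length(vals) == 0L) c(mean = NA_real_, n = 0) else
    c(mean = mean(vals), n = length(vals))
}

#' Network-wise average positive correlations
#'
#' For each selected network, the mean positive Fisher z over within-network
#' ROI pairs and over pairs joining that network's ROIs with all other
#' selected networks' ROIs. Negative and masked cells are excluded from both
#' numerator and denominator (set to `NA` before averaging). Each
#' cross-network cell therefore contributes to the between-network means of
#' both networks it joins.
#'
#' @param C A `connectivity_matrix`.
#' @param P A `network_partition`.
#' @return Data frame with one row per (network, metric) where metric is
#'   `within_pos` or `between_pos`; columns `network`, `metric`, `value`,
#'   `n_cells`. `value` is `NA` when no qualifying cell exists.
#' @export
network_positive_means <- function(C, P) {
  cc <- .net_cells(C, P)
  res <- lapply(P$networks, function(k) {
    ink <- cc$network == k
    within <- .cell_mean(cc$z, outer(ink, ink, "&"), "pos")
    between <- .cell_mean(cc$z, outer(ink, !ink, "&") | outer(!ink, ink, "&"),
                          "pos")
    data.frame(network = k,
               metric = c("within_pos", "between_pos"),
               value = c(within[["mean"]], between[["mean"]]),
               n_cells = c(within[["n"]], between[["n"]]))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Network-wise average negative correlations
#'
#' Mirror of [network_positive_means()] with signs flipped. Within-network
#' negative means are computed but flagged `for_analysis = FALSE`: few
#' within-network correlations are negative and their interpretation is
#' unclear, so only the between-network negative means enter group analyses.
#'
#' @inheritParams network_positive_means
#' @return Data frame with columns `network`, `metric`
#'   (`within_neg`/`between_neg`), `value`, `n_cells`, `for_analysis`.
#' @export
network_negative_means <- function(C, P) {
  cc <- .net_cells(C, P)
  res <- lapply(P$networks, function(k) {
    ink <- cc$network == k
    within <- .cell_mean(cc$z, outer(ink, ink, "&"), "neg")
    between <- .cell_mean(cc$z, outer(ink, !ink, "&") | outer(!ink, ink, "&"),
                          "neg")
    data.frame(network = k,
               metric = c("within_neg", "between_neg"),
               value = c(within[["mean"]], between[["mean"]]),
               n_cells = c(within[["n"]], between[["n"]]),
               for_analysis = c(FALSE, TRUE))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Whole-brain system segregation
#'
#' System segregation SS = (z_within - z_between) / z_within, where z_within
#' is the mean Fisher z over all within-network ROI pairs pooled across the
#' selected networks and z_between the mean over all between-network pairs.
#' Only positive correlations are considered: negative cells are set to zero
#' and, under the default `"zeroed-in-denominator"` variant, retained in the
#' cell counts (following the metric's original construction). The
#' `"positives-only"` variant instead drops negative cells entirely, as in
#' the per-network averaging procedure.
#'
#' Higher SS means more functionally independent networks; SS <= 1 whenever
#' z_within > 0 and z_between >= 0.
#'
#' @inheritParams network_positive_means
#' @param variant `"zeroed-in-denominator"` (default) or `"positives-only"`.
#' @param pooling `"pooled"` (default; cell-weighted mean over all cells) or
#'   `"network-weighted"` (mean of per-network means).
#' @return List of class `segregation_result` with `ss`, `zbar_within`,
#'   `zbar_between`, `variant` and `pooling`.
#' @export
system_segregation <- function(C, P,
                               variant = c("zeroed-in-denominator",
                                           "positives-only"),
                               pooling = c("pooled", "network-weighted")) {
  variant <- match.arg(variant)
  pooling <- match.arg(pooling)
  cc <- .net_cells(C, P)
  z <- cc$z
  if (variant == "zeroed-in-denominator") {
    z[!is.na(z) & z < 0] <- 0
  } else {
    z[!is.na(z) & z < 0] <- NA_real_
  }
  nets <- cc$network
  same <- outer(nets, nets, "==")
  ut <- upper.tri(z)
  if (pooling == "pooled") {
    zw <- mean(z[same & ut], na.rm = TRUE)
    zb <- mean(z[!same & ut], na.rm = TRUE)
  } else {
    per_w <- vapply(P$networks, function(k) {
      ink <- nets == k
      mean(z[outer(ink, ink, "&") & ut], na.rm = TRUE)
    }, numeric(1))
    per_b <- vapply(P$networks, function(k) {
      ink <- nets == k
      sel <- (outer(ink, !ink, "&") | outer(!ink, ink, "&")) & ut
      mean(z[sel], na.rm = TRUE)
    }, numeric(1))
    zw <- mean(per_w, na.rm = TRUE)
    zb <- mean(per_b, na.rm = TRUE)
  }
  if (!is.finite(zw) || zw <= 0)
    stop("system segregation undefined: zbar_within <= 0")
  structure(list(ss = (zw - zb) / zw, zbar_within = zw, zbar_between = zb,
                 variant = variant, pooling = pooling),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("system segregation: SS = %.4f (z_within %.4f, z_between %.4f; %s, %s)\n",
              x$ss, x$zbar_within, x$zbar_between, x$variant, x$pooling))
  invisible(x)
}
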