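#' @keywords internal
#' @useDynLib netseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# The ten functional networks used in all analyses, with their ROI counts in
# the 264-ROI parcellation. Order fixed: it defines factor level order in all
# downstream tables.
.NETSEG_NETWORKS <- c(Hand = 30L, Vis = 31L, Mouth = 5L, Aud = 13L, DMN = 58L,
                      Sal = 18L, CO = 14L, FP = 25L, DAN = 11L, VAN = 9L)

#' Names of the ten analysis networks
#'
#' The controlled vocabulary of network labels: somatomotor hand (Hand),
#' visual (Vis), somatomotor mouth (Mouth), auditory (Aud), default mode
#' (DMN), salience (Sal), cingulo-opercular (CO), frontoparietal (FP),
#' dorsal attention (DAN) and ventral attention (VAN). ROIs outside these
#' networks carry the label `"unassigned"`.
#'
#' @return Character vector of the ten network names, in canonical order.
#' @export
analysis_networks <- function() names(.NETSEG_NETWORKS)

#' ROI counts per analysis network
#'
#' @return Named integer vector of per-network ROI counts (sums to 214).
#' @export
network_sizes <- function() .NETSEG_NETWORKS

#' Path to the bundled synthetic 264-ROI atlas fixture
#'
#' The bundled atlas reproduces the ten-network label counts of the 264-ROI
#' functional parcellation, but its coordinates are synthetic: ROIs sit on a
#' 24-mm grid, so no pair is closer than the default 20-mm proximity
#' threshold and the fixture's proximity-exclusion set is empty. Tests that
#' exercise proximity masking construct closer ROIs explicitly.
#'
#' @return Path to a tab-separated atlas table.
#' @export
netseg_atlas_file <- function() {
  system.file("extdata", "power264_synthetic_atlas.tsv", package = "netseg",
              mustWork = TRUE)
}

#' Load and validate an ROI atlas table
#'
#' Reads a delimited text table with columns `roi_id`, `x`, `y`, `z`
#' (MNI coordinates, millimetres) and `network`. Tab- and comma-separated
#' files are both accepted. Rows are re-ordered by `roi_id`.
#'
#' @param path Path to the atlas table.
#' @return A `roi_atlas`: a data frame with columns `roi_id` (integer),
#'   `x`, `y`, `z` (numeric, mm) and `network` (character).
#' @export
#' @examples
#' atlas <- load_atlas(netseg_atlas_file())
#' nrow(atlas)  # 264
load_atlas <- function(path) {
  if (!file.exists(path)) stop("atlas file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("atlas format error: empty file: ", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("roi_id", "x", "y", "z", "network")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("atlas format error: missing column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0L) stop("atlas format error: no data rows")
  if (anyDuplicated(df$roi_id))
    stop("atlas validation error: duplicate roi_id: ",
         paste(unique(df$roi_id[duplicated(df$roi_id)]), collapse = ", "))
  df <- df[order(df$roi_id), required]
  if (!all(df$roi_id == seq_len(nrow(df))))
    stop("atlas validation error: roi_id must be contiguous 1..N")
  vocab <- c(analysis_networks(), "unassigned")
  bad <- setdiff(unique(df$network), vocab)
  if (length(bad) > 0L)
    stop("atlas validation error: unknown network label(s): ",
         paste(bad, collapse = ", "))
  df$roi_id <- as.integer(df$roi_id)
  for (v in c("x", "y", "z")) df[[v]] <- as.numeric(df[[v]])
  rownames(df) <- NULL
  class(df) <- c("roi_atlas", "data.frame")
  df
}

#' Restrict an atlas to a set of analysis networks
#'
#' Builds the network partition used by all averaging and graph analyses.
#' ROIs whose label is not among `names` (including `"unassigned"` ROIs)
#' are dropped from the partition; by default they are excluded everywhere,
#' graph construction included, so node sets match the averaging set.
#'
#' @param atlas A `roi_atlas` from [load_atlas()].
#' @param names Character vector of network names to keep; defaults to the
#'   ten analysis networks.
#' @return A `network_partition` list with elements `roi_id` (integer vector),
#'   `network` (character vector parallel to `roi_id`), `networks` (the
#'   ordered selection) and `sizes` (named counts).
#' @export
select_networks <- function(atlas, names = analysis_networks()) {
  stopifnot(inherits(atlas, "roi_atlas"))
  if (length(names) == 0L) stop("network selection must be non-empty")
  vocab <- analysis_networks()
  bad <- setdiff(names, vocab)
  if (length(bad) > 0L)
    stop("unknown network name(s): ", paste(bad, collapse = ", "))
  absent <- setdiff(names, unique(atlas$network))
  if (length(absent) > 0L)
    stop("network(s) not present in atlas: ", paste(absent, collapse = ", "))
  keep <- atlas$network %in% names
  part <- list(
    roi_id = atlas$roi_id[keep],
    network = atlas$network[keep],
    networks = names,
    sizes = vapply(names, function(nm) sum(atlas$network == nm), integer(1))
  )
  class(part) <- "network_partition"
  part
}

#' @export
print.network_partition <- function(x, ...) {
  cat("network_partition:", length(x$roi_id), "ROIs in",
      length(x$networks), "networks\n")
  print(x$sizes)
  invisible(x)
}

#' Geometric proximity exclusion pairs
#'
#' ROI pairs whose centres lie within `threshold_mm` of each other are
#' excluded from all correlation analyses, to avoid inflation by shared
#' signal between overlapping spheres. "Within" is interpreted strictly
#' (`d < threshold_mm`); pairs exactly at the boundary are retained. Set
#' `strict = FALSE` for the `<=` convention.
#'
#' @param atlas A `roi_atlas`.
#' @param threshold_mm Distance threshold in millimetres (default 20).
#' @param strict Logical; if `TRUE` (default) exclude pairs with
#'   `d < threshold_mm`, else `d <= threshold_mm`.
#' @return Integer matrix with two columns `i`, `j` (`i < j`), one row per
#'   excluded unordered ROI pair. Zero rows when no pair is too close.
#' @export
proximity_exclusion_pairs <- function(atlas, threshold_mm = 20,
                                      strict = TRUE) {
  stopifnot(inherits(atlas, "roi_atlas"), threshold_mm > 0)
  xyz <- as.matrix(atlas[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite ROI coordinate in atlas")
  d <- as.matrix(stats::dist(xyz))
  hit <- if (strict) d < threshold_mm else d <= threshold_mm
  hit[lower.tri(hit, diag = TRUE)] <- FALSE
  idx <- which(hit, arr.ind = TRUE)
  pairs <- cbind(i = atlas$roi_id[idx[, 1]], j = atlas$roi_id[idx[, 2]])
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}
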