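#' AAL-90 region table
#'
#' The 90 cortical and subcortical regions of the Automated Anatomical
#' Labeling atlas, re-indexed so that nodes 1..45 form the left and 46..90 the
#' right hemisphere (homologous regions are `k` and `k + 45`). The auditory
#' cortex is "Temporal Sup" (nodes 41 and 86).
#'
#' @return A data frame with columns `node`, `region`, `lobe`, `hemisphere`.
#' @export
aal90_regions <- function() {
  region <- c("Precentral", "Frontal Sup", "Frontal Sup Orb", "Frontal Mid",
              "Frontal Mid Orb", "Frontal Inf Oper", "Frontal Inf Tri",
              "Frontal Inf Orb", "Rolandic Oper", "Supp Motor Area",
              "Olfactory", "Frontal Sup Medial", "Frontal Med Orb", "Rectus",
              "Insula", "Cingulum Ant", "Cingulum Mid", "Cingulum Post",
              "Hippocampus", "ParaHippocampal", "Amygdala", "Calcarine",
              "Cuneus", "Lingual", "Occipital Sup", "Occipital Mid",
              "Occipital Inf", "Fusiform", "Postcentral", "Parietal Sup",
              "Parietal Inf", "Supramarginal", "Angular", "Precuneus",
              "Paracentral Lobule", "Caudate", "Putamen", "Pallidum",
              "Thalamus", "Heschl", "Temporal Sup", "Temporal Pole Sup",
              "Temporal Mid", "Temporal Pole Mid", "Temporal Inf")
  lobe <- c("Central region", "Frontal lobe", "Frontal lobe", "Frontal lobe",
            "Frontal lobe", "Frontal lobe", "Frontal lobe", "Frontal lobe",
            "Central Region", "Frontal lobe", "Frontal lobe", "Frontal lobe",
            "Frontal lobe", "Frontal lobe", "Insula", "Limbic lobe",
            "Limbic lobe", "Limbic lobe", "Limbic lobe", "Limbic lobe",
            "Sub cort. gray nuc", "Occipital lobe", "Occipital lobe",
            "Occipital lobe", "Occipital lobe", "Occipital lobe",
            "Occipital lobe", "Occipital lobe", "Central region",
            "Parietal lobe", "Parietal lobe", "Parietal lobe",
            "Parietal lobe", "Parietal lobe", "Frontal lobe",
            "Sub cort. gray nuc", "Sub cort. gray nuc", "Sub cort. gray nuc",
            "Sub cort. gray nuc", "Temporal lobe", "Temporal lobe",
            "Limbic lobe", "Temporal lobe", "Limbic lobe", "Temporal lobe")
  data.frame(node = 1:90,
             region = rep(region, 2),
             lobe = rep(lobe, 2),
             hemisphere = rep(c("L", "R"), each = 45),
             stringsAsFactors = FALSE)
}

#' Hemisphere of a node
#'
#' @param k Node index(es), 1..90.
#' @return `"L"` for `k <= 45`, `"R"` otherwise.
#' @export
hemisphere_of <- function(k) {
  if (any(k < 1 | k > 90)) stop("node index must lie in 1..90")
  ifelse(k <= 45, "L", "R")
}

#' Auditory-cortex node indices
#'
#' @return The 1-based indices of the "Temporal Sup" regions, one per
#'   hemisphere.
#' @export
auditory_nodes <- function() c(41L, 86L)

.new_brain_network <- function(adjacency) {
  regions <- aal90_regions()
  structure(list(adjacency = adjacency,
                 hemisphere = regions$hemisphere,
                 region_names = regions$region,
                 auditory_nodes = auditory_nodes()),
            class = "brain_network")
}

.validate_adjacency <- function(A, normalize = TRUE) {
  if (!is.matrix(A) || nrow(A) != 90 || ncol(A) != 90)
    stop("adjacency must be a 90 x 90 matrix, got ",
         paste(dim(A), collapse = " x "))
  if (any(!is.finite(A))) stop("adjacency contains non-finite values")
  if (any(A < 0)) stop("adjacency weights must be non-negative")
  asym <- max(abs(A - t(A)))
  if (asym > 1e-9)
    stop("adjacency is asymmetric (max |A - t(A)| = ", format(asym), ")")
  if (asym > 0) {
    warning("symmetrizing a near-symmetric adjacency (max asymmetry ",
            format(asym), ")")
    A <- (A + t(A)) / 2
  }
  diag(A) <- 0
  if (normalize && max(A) > 0) A <- A / max(A)
  unname(A)
}

#' Load a 90-node weighted adjacency matrix
#'
#' Reads a 90 x 90 numeric CSV/TSV (no header), validates symmetry and
#' non-negativity, zeroes the diagonal, rescales so the maximum weight is 1,
#' and attaches the AAL-90 region labels (nodes 1..45 left hemisphere,
#' 46..90 right).
#'
#' @param path Path to the matrix file.
#' @param sep Field separator (`""` auto-detects whitespace vs comma).
#' @return A `brain_network` object.
#' @export
load_adjacency <- function(path, sep = ",") {
  A <- as.matrix(read.table(path, sep = sep, header = FALSE))
  storage.mode(A) <- "double"
  .new_brain_network(.validate_adjacency(A))
}

#' Write a brain network's adjacency to CSV
#'
#' Full double precision, so that a generate/write/load round trip is
#' bitwise exact.
#'
#' @param network A `brain_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(network, path) {
  A <- network$adjacency
  lines <- apply(A, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Generate a synthetic two-hemisphere connectome
#'
#' Surrogate for a DTI-derived AAL-90 structural network: symmetric,
#' non-negative, zero diagonal, with the characteristic hemispheric block
#' structure — denser and stronger connections inside each 45-node hemisphere
#' block than between hemispheres — plus elevated homologous pair weights
#' (k, k + 45) mimicking the empirical anti-diagonal (callosal connections).
#' Weights are log-normal and rescaled so the maximum is 1. Deterministic
#' under `seed`.
#'
#' @param seed Integer seed.
#' @param intra_density Edge density inside each hemisphere block (0, 1].
#' @param inter_density Edge density between hemispheres (0, 1].
#' @param intra_strength Mean weight multiplier of intra-hemispheric edges
#'   relative to inter-hemispheric ones.
#' @param homologous_strength Weight multiplier for homologous pairs.
#' @param weight_sdlog Log-normal sd of raw edge weights; the heavy tail of
#'   empirical streamline counts is what keeps the reference coupling in the
#'   partially synchronized regime.
#' @param auditory_hub Multiplier applied to the rows/columns of the
#'   auditory nodes (41, 86): the superior temporal region is among the most
#'   strongly connected AAL parcels in tractography, and this hub structure
#'   gives an auditory stimulus its leverage over the collective dynamics.
#' @return A `brain_network`.
#' @examples
#' net <- generate_synthetic_connectome(seed = 1)
#' @export
generate_synthetic_connectome <- function(seed, intra_density = 0.35,
                                          inter_density = 0.12,
                                          intra_strength = 2,
                                          homologous_strength = 6,
                                          weight_sdlog = 1.5,
                                          auditory_hub = 2) {
  if (intra_density <= 0 || intra_density > 1 ||
      inter_density <= 0 || inter_density > 1)
    stop("densities must lie in (0, 1]")
  set.seed(as.integer(seed))
  n <- 90
  hemi <- rep(c("L", "R"), each = 45)
  A <- matrix(0, n, n)
  for (k in 1:(n - 1)) {
    for (j in (k + 1):n) {
      intra <- hemi[k] == hemi[j]
      p <- if (intra) intra_density else inter_density
      if (runif(1) < p) {
        w <- exp(rnorm(1, sd = weight_sdlog))
        if (intra) w <- w * intra_strength
        A[k, j] <- w
        A[j, k] <- w
      }
    }
  }
  for (k in 1:45) {
    w <- exp(rnorm(1, sd = weight_sdlog)) * homologous_strength
    A[k, k + 45] <- w
    A[k + 45, k] <- w
  }
  if (auditory_hub != 1) {
    aud <- auditory_nodes()
    A[aud, ] <- A[aud, ] * auditory_hub
    A[, aud] <- t(A[aud, ])
  }
  A <- A / max(A)
  .new_brain_network(.validate_adjacency(A))
}

#' @export
print.brain_network <- function(x, ...) {
  A <- x$adjacency
  intra <- outer(x$hemisphere, x$hemisphere, "==")
  diag(intra) <- NA
  cat(sprintf(paste0("<brain_network> 90 nodes (45 L / 45 R), %d edges, ",
                     "mean intra %.3g / inter %.3g, auditory nodes %s\n"),
              sum(A[upper.tri(A)] > 0),
              mean(A[which(intra)]), mean(A[which(!intra)]),
              paste(x$auditory_nodes, collapse = ", ")))
  invisible(x)
}

#' Write region labels as a JSON sidecar
#'
#' @param network A `brain_network`.
#' @param path Output path for a JSON file with node, region, lobe and
#'   hemisphere fields.
#' @return `path`, invisibly.
#' @export
write_region_labels <- function(network, path) {
  jsonlite::write_json(aal90_regions(), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
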