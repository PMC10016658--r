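#' The 30-region canine brain atlas
#'
#' Returns the parcellation used throughout the package: 14 bilateral
#' cortical/subcortical regions (left hemisphere nodes 1-14, right
#' hemisphere nodes 15-28, homotopic partner = index + 14) plus two
#' midline structures, the mesencephalon (29) and diencephalon (30).
#' The atlas also carries the a-priori anxiety circuit (amygdala,
#' frontal lobe, hippocampus, mesencephalon, thalamus) and the vermis,
#' which serves as the negative-control region in nodal comparisons.
#'
#' @return An object of class `fc_atlas`: a list with components
#'   \describe{
#'     \item{regions}{data.frame with `index` (1-30), `region` (region
#'       name, shared by homotopic pairs), `hemisphere` (`"L"`, `"R"` or
#'       `"midline"`) and `node` (unique node label, e.g.
#'       `"amygdala L"`).}
#'     \item{homotopic}{two-column integer matrix of (L, R) node index
#'       pairs for the 14 bilateral regions.}
#'     \item{circuit_regions}{character vector of the five anxiety-circuit
#'       region names.}
#'     \item{control_region}{`"vermis"`.}
#'   }
#' @examples
#' atl <- canine_atlas()
#' nrow(atl$regions)           # 30
#' atlas_nodes(atl, "amygdala")  # c(12, 26)
#' @export
canine_atlas <- function() {
  bilateral <- c(
    "temporal lobe", "parietal lobe", "occipital lobe", "frontal lobe",
    "anterior cingulate gyrus", "posterior cingulate gyrus",
    "hippocampus", "thalamus", "caudate nucleus", "piriform lobe",
    "insular cortex", "amygdala", "cerebral hemisphere", "vermis"
  )
  regions <- data.frame(
    index = 1:30,
    region = c(bilateral, bilateral, "mesencephalon", "diencephalon"),
    hemisphere = c(rep("L", 14), rep("R", 14), "midline", "midline"),
    stringsAsFactors = FALSE
  )
  regions$node <- ifelse(regions$hemisphere == "midline", regions$region,
                         paste(regions$region, regions$hemisphere))
  structure(
    list(
      regions = regions,
      homotopic = cbind(L = 1:14, R = 15:28),
      circuit_regions = c("amygdala", "frontal lobe", "hippocampus",
                          "mesencephalon", "thalamus"),
      control_region = "vermis"
    ),
    class = "fc_atlas"
  )
}

#' @export
print.fc_atlas <- function(x, ...) {
  cat("Canine functional-connectivity atlas:", nrow(x$regions), "nodes\n")
  cat("  bilateral regions:", nrow(x$homotopic), "\n")
  cat("  anxiety circuit:", paste(x$circuit_regions, collapse = ", "), "\n")
  cat("  control region:", x$control_region, "\n")
  invisible(x)
}

#' Node indices of an atlas region
#'
#' @param atlas an `fc_atlas`.
#' @param region region name (e.g. `"amygdala"`); matched against the
#'   hemisphere-free region name.
#' @return Integer vector of node indices: two for bilateral regions, one
#'   for midline regions.
#' @export
atlas_nodes <- function(atlas, region) {
  stopifnot(inherits(atlas, "fc_atlas"))
  idx <- atlas$regions$index[atlas$regions$region == region]
  if (length(idx) == 0L) {
    stop("unknown atlas region: '", region, "'", call. = FALSE)
  }
  idx
}

#' Node labels of the atlas, in node order
#'
#' @param atlas an `fc_atlas`.
#' @return Character vector of 30 unique node labels.
#' @export
atlas_node_names <- function(atlas) {
  stopifnot(inherits(atlas, "fc_atlas"))
  atlas$regions$node
}

#' Region-level names (bilateral pairs collapsed)
#'
#' @param atlas an `fc_atlas`.
#' @return Character vector of the 16 distinct region names.
#' @export
atlas_region_names <- function(atlas) {
  stopifnot(inherits(atlas, "fc_atlas"))
  unique(atlas$regions$region)
}

#' Node index pairs spanning two regions
#'
#' Expands a region-level connection into its constituent node pairs:
#' bilateral x bilateral gives 4 pairs, bilateral x midline 2, midline x
#' midline 1; `region_a == region_b` requests the homotopic (L-R) pair
#' of one bilateral region.
#'
#' @param atlas an `fc_atlas`.
#' @param region_a,region_b region names.
#' @return Two-column integer matrix of node index pairs.
#' @export
region_pair_nodes <- function(atlas, region_a, region_b) {
  ia <- atlas_nodes(atlas, region_a)
  ib <- atlas_nodes(atlas, region_b)
  if (region_a == region_b) {
    if (length(ia) != 2L) {
      stop("homotopic pair requested for midline region '", region_a, "'",
           call. = FALSE)
    }
    return(matrix(ia, ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  pairs <- expand.grid(i = ia, j = ib)
  as.matrix(pairs)
}
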