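#' @keywords internal
"_PACKAGE"

# Enumerations shared across the package. Compartment and direction labels
# follow the anatomical sampling grid: an oval disc cut into 7 lateral and
# 5 anteroposterior segments, with the nucleus pulposus (NP) shared at the
# centre of both axes and the inner annulus (IAF) present only laterally.
AGE_GROUPS    <- c("young", "aged")
DISC_LEVELS   <- c("L3/4", "L4/5", "L5/S1")
COMPARTMENTS  <- c("NP", "NP/IAF", "IAF", "OAF")
DIRECTIONS    <- c("left", "right", "anterior", "posterior", "central")
MATRISOME_CLASSES <- c("collagen", "proteoglycan", "glycoprotein",
                       "ecm_regulator", "ecm_affiliated", "secreted_factor",
                       "non_matrisome")
CORE_MATRISOME <- c("collagen", "proteoglycan", "glycoprotein")
DEP_STRATEGIES <- c("statistical", "exclusive", "fold_change", "none")

#' Canonical sampling locations of one disc
#'
#' The 11 locations per disc: four outer-annulus (OAF) segments (left, right,
#' anterior, posterior), two inner-annulus (IAF) segments (lateral axis only),
#' four NP/IAF transition segments, and the central NP. Lateral positions run
#' 1--7 (left OAF to right OAF), anteroposterior positions 1--5 (anterior OAF
#' to posterior OAF); the NP carries both (4 and 3).
#'
#' @return A data frame with columns `location`, `compartment`, `direction`,
#'   `lateral_pos`, `ap_pos`.
#' @export
disc_locations <- function() {
  data.frame(
    location    = c("OAF_L", "IAF_L", "NPIAF_L", "NP", "NPIAF_R", "IAF_R",
                    "OAF_R", "OAF_A", "NPIAF_A", "NPIAF_P", "OAF_P"),
    compartment = c("OAF", "IAF", "NP/IAF", "NP", "NP/IAF", "IAF", "OAF",
                    "OAF", "NP/IAF", "NP/IAF", "OAF"),
    direction   = c("left", "left", "left", "central", "right", "right",
                    "right", "anterior", "anterior", "posterior", "posterior"),
    lateral_pos = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, NA, NA, NA, NA),
    ap_pos      = c(NA, NA, NA, 3L, NA, NA, NA, 1L, 2L, 4L, 5L),
    stringsAsFactors = FALSE
  )
}

#' Validate profile metadata
#'
#' Checks the per-profile anatomical labels: enum membership, uniqueness of
#' profile ids, and the axis rule (exactly one of `lateral_pos`/`ap_pos` is
#' set, except the NP which is central to both axes; IAF occurs only on the
#' lateral axis).
#'
#' @param meta Data frame with columns `profile_id`, `age_group`, `level`,
#'   `compartment`, `direction`, `lateral_pos`, `ap_pos`.
#' @return `meta`, invisibly, after validation.
#' @export
validate_profile_meta <- function(meta) {
  req <- c("profile_id", "age_group", "level", "compartment", "direction",
           "lateral_pos", "ap_pos")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$profile_id))
    stop("duplicate profile_id values in metadata")
  chk <- function(col, allowed) {
    bad <- setdiff(unique(meta[[col]]), allowed)
    if (length(bad))
      stop("unknown ", col, " label(s): ", paste(bad, collapse = ", "))
  }
  chk("age_group", AGE_GROUPS)
  chk("level", DISC_LEVELS)
  chk("compartment", COMPARTMENTS)
  chk("direction", DIRECTIONS)
  has_lat <- !is.na(meta$lateral_pos)
  has_ap  <- !is.na(meta$ap_pos)
  np <- meta$compartment == "NP"
  if (any(np & !(has_lat & has_ap)))
    stop("NP profiles must carry both lateral_pos and ap_pos (disc centre)")
  if (any(!np & has_lat & has_ap))
    stop("non-NP profiles must sit on exactly one axis")
  if (any(!np & !has_lat & !has_ap))
    stop("profile without an axis position: ",
         paste(meta$profile_id[!np & !has_lat & !has_ap], collapse = ", "))
  if (any(meta$compartment == "IAF" & !has_lat))
    stop("IAF profiles occur only on the lateral axis")
  if (any(has_lat & (meta$lateral_pos < 1 | meta$lateral_pos > 7)))
    stop("lateral_pos out of range 1-7")
  if (any(has_ap & (meta$ap_pos < 1 | meta$ap_pos > 5)))
    stop("ap_pos out of range 1-5")
  invisible(meta)
}

#' Construct an abundance matrix
#'
#' Container for a protein-by-profile matrix of log2 LFQ values. Missing
#' entries (proteins not detected in a profile) are `NA`, never zero: the
#' differential-expression logic branches on detection counts, so missingness
#' is kept explicit. The observation mask is derived as `!is.na(values)`.
#'
#' @param values Numeric matrix, proteins in rows, profiles in columns;
#'   `NA` marks a missing (undetected) entry.
#' @param proteins Data frame with one row per protein: `accession`,
#'   `gene_symbol`, `matrisome_class`.
#' @param profiles Profile metadata (see [validate_profile_meta()]).
#' @return An object of class `abundance_matrix` with elements `values`,
#'   `mask`, `proteins`, `profiles`.
#' @export
abundance_matrix <- function(values, proteins, profiles) {
  values <- as.matrix(values)
  if (nrow(values) != nrow(proteins))
    stop("values/proteins dimension mismatch")
  if (ncol(values) != nrow(profiles))
    stop("values/profiles dimension mismatch")
  if (anyDuplicated(proteins$accession))
    stop("duplicate protein accessions")
  bad <- setdiff(unique(proteins$matrisome_class), MATRISOME_CLASSES)
  if (length(bad))
    stop("unknown matrisome class(es): ", paste(bad, collapse = ", "))
  validate_profile_meta(profiles)
  if (any(!is.finite(values) & !is.na(values)))
    stop("observed values must be finite")
  rownames(values) <- proteins$accession
  colnames(values) <- profiles$profile_id
  structure(
    list(values = values, mask = !is.na(values),
         proteins = proteins, profiles = profiles),
    class = "abundance_matrix"
  )
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf(
    "abundance_matrix: %d proteins x %d profiles (%.1f%% observed)\n",
    nrow(x$values), ncol(x$values), 100 * mean(x$mask)))
  obs <- x$values[x$mask]
  if (length(obs))
    cat(sprintf("  log2 LFQ range: %.1f - %.1f\n", min(obs), max(obs)))
  cat("  ages: ", paste(unique(x$profiles$age_group), collapse = ", "),
      "; levels: ", paste(unique(x$profiles$level), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Subset an abundance matrix by protein and/or profile
#'
#' @param mat An `abundance_matrix`.
#' @param proteins Row selector (indices, logical, or accessions).
#' @param profiles Column selector (indices, logical, or profile ids).
#' @return The subsetted `abundance_matrix`.
#' @export
subset_abundance <- function(mat, proteins = NULL, profiles = NULL) {
  pi <- if (is.null(proteins)) seq_len(nrow(mat$values)) else proteins
  if (is.character(pi)) pi <- match(pi, mat$proteins$accession)
  ci <- if (is.null(profiles)) seq_len(ncol(mat$values)) else profiles
  if (is.character(ci)) ci <- match(ci, mat$profiles$profile_id)
  abundance_matrix(mat$values[pi, ci, drop = FALSE],
                   mat$proteins[pi, , drop = FALSE],
                   mat$profiles[ci, , drop = FALSE])
}
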