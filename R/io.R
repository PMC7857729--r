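# Readers/writers for the plain-text formats used throughout: TSV with a
# header row, UTF-8, and the MaxQuant proteinGroups column conventions for
# raw LFQ exports.

#' Read an LFQ protein-by-profile matrix
#'
#' Two dialects are supported. `maxquant_proteingroups` expects a
#' proteinGroups-style TSV with sample columns prefixed `"LFQ intensity "`;
#' intensities are on the raw scale, zeros encode non-detection and become
#' `NA`, remaining values are log2-transformed, and contaminant (`CON__`),
#' decoy (`REV__`) and "Only identified by site" rows are dropped.
#' `plain_tsv` expects one protein per row (first column the identifier) and
#' one profile per column, already on log2 scale unless `log2 = FALSE`.
#'
#' @param path TSV file path.
#' @param dialect `"maxquant_proteingroups"` or `"plain_tsv"`.
#' @param log2 For `plain_tsv` only: whether values are already log2
#'   (default `TRUE`); if `FALSE` they are log2-transformed with zeros
#'   treated as missing.
#' @param profiles Optional profile metadata to attach; defaults to minimal
#'   placeholder metadata (useful for matrices without anatomical labels).
#' @param annotation Optional matrisome annotation (named vector from
#'   [read_matrisome_annotation()]) used to classify proteins.
#' @return An [abundance_matrix()].
#' @export
read_lfq_matrix <- function(path,
                            dialect = c("maxquant_proteingroups", "plain_tsv"),
                            log2 = TRUE, profiles = NULL, annotation = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)

  if (dialect == "maxquant_proteingroups") {
    idcol <- if ("Protein IDs" %in% names(tab)) "Protein IDs" else names(tab)[1]
    lfq <- grep("^LFQ intensity ", names(tab), value = TRUE)
    if (!length(lfq)) stop("no 'LFQ intensity ' columns found in ", path)
    acc <- tab[[idcol]]
    keep <- !grepl("^(CON__|REV__)", acc)
    if ("Only identified by site" %in% names(tab))
      keep <- keep & !(tab[["Only identified by site"]] %in% c("+", "TRUE"))
    if ("Reverse" %in% names(tab)) keep <- keep & tab[["Reverse"]] != "+"
    if ("Potential contaminant" %in% names(tab))
      keep <- keep & tab[["Potential contaminant"]] != "+"
    tab <- tab[keep, , drop = FALSE]
    acc <- acc[keep]
    vals <- check_numeric_cells(tab[lfq], path)
    vals[vals == 0] <- NA          # zero intensity = not detected
    vals <- log2(vals)
    colnames(vals) <- sub("^LFQ intensity ", "", lfq)
    gene <- if ("Gene names" %in% names(tab))
      vapply(strsplit(tab[["Gene names"]], ";"), `[`, "", 1) else acc
  } else {
    acc <- as.character(tab[[1]])
    # optional annotation columns written by write_lfq_matrix
    gene <- if ("gene_symbol" %in% names(tab))
      as.character(tab[["gene_symbol"]]) else acc
    cls0 <- if ("matrisome_class" %in% names(tab))
      as.character(tab[["matrisome_class"]]) else NULL
    drop_cols <- c(1L, which(names(tab) %in% c("gene_symbol",
                                               "matrisome_class")))
    vals <- check_numeric_cells(tab[-drop_cols], path)
    if (!log2) {
      vals[vals == 0] <- NA
      vals <- log2(vals)
    }
  }
  if (anyDuplicated(acc))
    stop("duplicate protein identifiers in ", path, ": ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  gene[is.na(gene) | gene == ""] <- acc[is.na(gene) | gene == ""]

  cls <- if (!is.null(annotation)) matrisome_class_of(gene, annotation)
         else if (dialect == "plain_tsv" && !is.null(cls0)) cls0
         else rep("non_matrisome", length(acc))
  proteins <- data.frame(accession = acc, gene_symbol = gene,
                         matrisome_class = cls, stringsAsFactors = FALSE)
  if (is.null(profiles)) profiles <- placeholder_meta(colnames(vals))
  abundance_matrix(vals, proteins, profiles)
}

check_numeric_cells <- function(df, path) {
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]) & df[[j]] != "NA" & df[[j]] != "")
    if (length(bad))
      stop(sprintf("non-numeric cell in %s at row %d, column '%s': '%s'",
                   path, bad[1], names(df)[j], df[[j]][bad[1]]))
    df[[j]] <- v
  }
  as.matrix(df)
}

# Minimal stand-in metadata when a matrix arrives without anatomical labels.
placeholder_meta <- function(ids) {
  data.frame(profile_id = ids, age_group = "young", level = "L3/4",
             compartment = "NP", direction = "central",
             lateral_pos = 4L, ap_pos = 3L, stringsAsFactors = FALSE)
}

#' Read profile metadata from TSV
#'
#' @param path TSV with columns `profile_id`, `age_group`, `level`,
#'   `compartment`, `direction`, `lateral_pos`, `ap_pos` (empty cells allowed
#'   in the position columns).
#' @return A validated metadata data frame.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  for (col in c("lateral_pos", "ap_pos"))
    meta[[col]] <- suppressWarnings(as.integer(meta[[col]]))
  validate_profile_meta(meta)
  meta
}

#' Write profile metadata to TSV
#' @param meta Metadata data frame.
#' @param path Output path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Category labels used by the matrisome project, mapped to internal classes.
MATRISOME_LABELS <- c(
  "Collagens"               = "collagen",
  "Proteoglycans"           = "proteoglycan",
  "ECM Glycoproteins"       = "glycoprotein",
  "ECM Regulators"          = "ecm_regulator",
  "ECM-affiliated Proteins" = "ecm_affiliated",
  "Secreted Factors"        = "secreted_factor"
)

#' Read a matrisome annotation table
#'
#' Expects at least two columns: gene symbol and matrisome category, with the
#' category labels used by the matrisome project
#' (e.g. "Collagens", "Proteoglycans", "ECM Glycoproteins", "ECM Regulators",
#' "ECM-affiliated Proteins", "Secreted Factors"). Gene symbols are the join
#' key; duplicate symbols resolve first-wins with a warning.
#'
#' @param path TSV path; first column gene, second column category (or columns
#'   named `gene`/`category`, case-insensitive).
#' @return Named character vector mapping gene symbol to matrisome class.
#' @export
read_matrisome_annotation <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  nm <- tolower(names(tab))
  gcol <- if ("gene" %in% nm) which(nm == "gene")[1] else 1L
  ccol <- if ("category" %in% nm) which(nm == "category")[1] else 2L
  genes <- as.character(tab[[gcol]])
  cats  <- as.character(tab[[ccol]])
  unknown <- setdiff(unique(cats), names(MATRISOME_LABELS))
  if (length(unknown))
    stop("unknown matrisome category label(s): ",
         paste(unknown, collapse = ", "))
  if (anyDuplicated(genes)) {
    warning("duplicate gene symbols in matrisome annotation; first entry wins")
    keep <- !duplicated(genes)
    genes <- genes[keep]; cats <- cats[keep]
  }
  stats::setNames(unname(MATRISOME_LABELS[cats]), genes)
}

#' Look up matrisome classes for gene symbols
#'
#' @param genes Character vector of gene symbols.
#' @param annotation Named vector from [read_matrisome_annotation()].
#' @return Character vector of classes; unmapped genes are `non_matrisome`.
#' @export
matrisome_class_of <- function(genes, annotation) {
  cls <- unname(annotation[genes])
  cls[is.na(cls)] <- "non_matrisome"
  cls
}

#' Write / read a result table
#'
#' Long-format result tables (one row per protein and comparison or factor)
#' round-trip through TSV bit-identically.
#'
#' @param table Data frame of results.
#' @param path TSV path.
#' @return `write_result_table` returns the path invisibly;
#'   `read_result_table` the data frame.
#' @export
write_result_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if ("strategy" %in% names(tab)) {
    bad <- setdiff(unique(tab$strategy), DEP_STRATEGIES)
    if (length(bad))
      stop("unknown strategy label(s): ", paste(bad, collapse = ", "))
  }
  tab
}

#' Write an abundance matrix (values + metadata) to TSV
#'
#' Values are written on log2 scale with `NA` for missing entries (never 0),
#' one protein per row, profiles in columns.
#'
#' @param mat An `abundance_matrix`.
#' @param path Values TSV path.
#' @param meta_path Optional metadata TSV path.
#' @export
write_lfq_matrix <- function(mat, path, meta_path = NULL) {
  out <- data.frame(accession = mat$proteins$accession,
                    gene_symbol = mat$proteins$gene_symbol,
                    matrisome_class = mat$proteins$matrisome_class,
                    mat$values, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  if (!is.null(meta_path)) write_metadata(mat$profiles, meta_path)
  invisible(path)
}
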