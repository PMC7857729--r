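# Shared fixture builders: tiny abundance matrices with controllable
# metadata, and on-disk TSVs in the supported dialects.

# n profiles with explicit compartments/ages; positions filled to satisfy
# the axis invariants (non-NP profiles on the lateral axis).
fixture_meta <- function(n, age = "young", compartment = "NP",
                         level = "L3/4") {
  age <- rep_len(age, n); compartment <- rep_len(compartment, n)
  level <- rep_len(level, n)
  lat <- ifelse(compartment == "NP", 4L, 1L)
  data.frame(profile_id = sprintf("S%02d", seq_len(n)),
             age_group = age, level = level, compartment = compartment,
             direction = ifelse(compartment == "NP", "central", "left"),
             lateral_pos = lat,
             ap_pos = ifelse(compartment == "NP", 3L, NA_integer_),
             stringsAsFactors = FALSE)
}

fixture_proteins <- function(n, class = "non_matrisome") {
  data.frame(accession = sprintf("P%03d", seq_len(n)),
             gene_symbol = sprintf("G%03d", seq_len(n)),
             matrisome_class = rep_len(class, n),
             stringsAsFactors = FALSE)
}

fixture_matrix <- function(values, meta = NULL, class = "non_matrisome") {
  values <- as.matrix(values)
  if (is.null(meta)) meta <- fixture_meta(ncol(values))
  abundance_matrix(values, fixture_proteins(nrow(values), class), meta)
}

# MaxQuant-style proteinGroups TSV
write_maxquant_fixture <- function(path) {
  tab <- data.frame(
    `Protein IDs` = c("P02452", "P21810", "CON__P02768", "REV__Q99999",
                      "P12111"),
    `Gene names` = c("COL1A1", "BGN", "ALB", "DECOY", "COL6A3;COL6A3b"),
    `Only identified by site` = c("", "", "", "", "+"),
    `LFQ intensity young_NP` = c(1048576, 0, 5, 7, 256),
    `LFQ intensity young_OAF` = c(2097152, 1024, 6, 8, 512),
    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_matrisome_fixture <- function(path) {
  tab <- data.frame(
    gene = c("ACAN", "COL2A1", "FN1", "TIMP1", "ANXA1", "ANGPTL2"),
    category = c("Proteoglycans", "Collagens", "ECM Glycoproteins",
                 "ECM Regulators", "ECM-affiliated Proteins",
                 "Secreted Factors"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# abundance matrix wrapper around the sparse-regression benchmark, mapped
# onto one age group of the 66-profile design
hydration_fixture <- function(x, y, age = "aged") {
  meta66 <- discproteome:::full_design_meta()
  meta <- meta66[meta66$age_group == age, ]
  prot <- data.frame(accession = colnames(x), gene_symbol = colnames(x),
                     matrisome_class = "glycoprotein",
                     stringsAsFactors = FALSE)
  mat <- abundance_matrix(t(x), prot,
                          meta[, setdiff(names(meta), "location")])
  list(mat = mat,
       intensities = data.frame(level = meta$level,
                                location = meta$location, intensity = y,
                                stringsAsFactors = FALSE))
}
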