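# External data drop-in

The cohort benchmark (`benchmark_counts()` and the corresponding acceptance
test) runs only when the processed 66-profile spatial LFQ matrix is placed
here as:

* `processed_spatial_matrix.tsv` — log2 values, first column `accession`,
  optional `gene_symbol` / `matrisome_class` columns, one profile per
  remaining column, `NA` for missing;
* `processed_spatial_metadata.tsv` — columns `profile_id`, `age_group`,
  `level`, `compartment`, `direction`, `lateral_pos`, `ap_pos`.

No third-party data is bundled with the package.
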