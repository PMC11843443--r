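# Small in-code fixtures shared across test files.

# localization data.frame with the given compartment probability per
# protein; everything else gets `background`
make_loc_df <- function(calls, background = 0.1) {
  cps <- compartments()
  rows <- lapply(names(calls), function(id) {
    p <- setNames(rep(background, 9), cps)
    p[calls[[id]]] <- 0.9
    as.data.frame(as.list(p), check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  cbind(data.frame(protein_id = names(calls), stringsAsFactors = FALSE), df)
}

# named call-set list shortcut
make_called <- function(...) {
  lapply(list(...), identity)
}

# a minimal valid age table data.frame
make_age_df <- function(gene_id, branch,
                        biotype = "protein_coding", chromosome = "2L") {
  data.frame(gene_id = gene_id,
             branch = factor(branch, levels = branch_labels()),
             biotype = biotype, chromosome = chromosome,
             stringsAsFactors = FALSE)
}

# presence row covering the default 8-clade map
make_presence_row <- function(present_idx) {
  cm <- default_clade_map()
  setNames(seq_len(nrow(cm)) %in% present_idx, cm$clade_id)
}
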