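# minimal data.frame construction for hot per-sweep paths (no name mangling,
# no deparse); columns must be equal-length atomic vectors
quick_df <- function(cols) {
  structure(cols, class = "data.frame",
            row.names = .set_row_names(length(cols[[1]])))
}
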