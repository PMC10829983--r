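# small in-code fixtures shared across test files

mk_table <- function(source, edge, target, ...) {
  triplet_table(data.frame(source = source, edge = edge, target = target,
                           ..., stringsAsFactors = FALSE))
}

# flat (source, edge, target) strings for set comparisons
row_strings <- function(table) {
  paste(table$source, table$edge, table$target, sep = " | ")
}
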