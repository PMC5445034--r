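# small fixture builders shared across test files

# a 14-char key block from a single letter (or any seed string)
kb <- function(x) {
  s <- paste(rep(as.character(x), 14), collapse = "")
  substr(s, 1, 14)
}

# challenge from parallel vectors of key blocks and ChemSpider IDs
make_challenge <- function(blocks, ids = seq_along(blocks), truth = NULL,
                           id = "c1", precursor = 300) {
  challenge(id,
            data.frame(chemspider_id = ids,
                       inchikey = paste0(blocks, "-UHFFFAOYSA-N"),
                       stringsAsFactors = FALSE),
            precursor_mz = precursor,
            truth_key_block = truth)
}

# flat two-column peak matrix
peaks <- function(mz, intensity) cbind(mz = mz, intensity = intensity)

# uniform weights table: every tool gets the same omega at every k
flat_weights <- function(tools, omega = 0.5, ks = c(1, 5, 10, 20)) {
  structure(
    data.frame(tool_name = rep(tools, each = length(ks)),
               k = rep(ks, length(tools)),
               omega = omega,
               stringsAsFactors = FALSE),
    class = c("sensitivity_weights", "data.frame"),
    k_use = 10, calibrated_on = list(label = "fixture", n = NA_integer_))
}
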