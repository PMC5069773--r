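# Small in-code fixtures shared across test files.

# one alignment hit row with sensible defaults
hit <- function(read, subject, bit, len = 150, pident = 97,
                sstart = NULL, send = NULL, sample = NULL) {
  out <- tibble::tibble(read_id = read, subject_id = subject,
                        pident = pident, align_length = len, bit_score = bit)
  if (!is.null(sstart)) {
    out$sstart <- sstart
    out$send <- send
  }
  if (!is.null(sample)) out$sample <- sample
  out
}

# two-family, two-genus toy taxonomy
toy_taxonomy <- function(blacklist = NULL, masks = NULL) {
  taxonomy(c(
    G1 = "Bacteria;Proteobacteria;Alphaproteobacteria;Rhodobacterales;Rhodobacteraceae;Roseovarius",
    G2 = "Bacteria;Proteobacteria;Alphaproteobacteria;Rhodobacterales;Rhodobacteraceae;Sulfitobacter",
    F2 = "Bacteria;Bacteroidetes;Flavobacteriia;Flavobacteriales;Flavobacteriaceae;Muricauda",
    EU = "Eukaryota;Bryozoa;Gymnolaemata;Cheilostomatida;Membraniporidae;Membranipora"
  ), blacklist = blacklist, masks = masks)
}

# bottle table with exact treatment means and no noise
exact_bottles <- function(light, dark, t0, n = 2, duration_h = 24, ...) {
  tibble::tibble(
    experiment_id = "e1",
    treatment = rep(c("light", "dark", "t0"), each = n),
    o2_umol_per_L = rep(c(light, dark, t0), each = n),
    duration_h = duration_h,
    ...
  )
}

# long abundance table from a named matrix (clades x samples)
long_table <- function(m, taxon = "clade") {
  tb <- tibble::as_tibble(m, rownames = taxon)
  out <- tidyr::pivot_longer(tb, -dplyr::all_of(taxon),
                             names_to = "sample", values_to = "proportion")
  out
}
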