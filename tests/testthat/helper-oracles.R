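# Brute-force interpreter of the switching rule, written directly from the
# verbal definition and kept independent of the package's caller: person
# switches A -> B if the first fill is A and, among fills after the first B
# fill, at least `threshold` are B; controls started on A but never switched
# consistently; everyone else is ineligible.
brute_force_status <- function(seq_ab, min_fills = 3, threshold = 0.5) {
  if (length(seq_ab) < min_fills) return("excluded")
  if (seq_ab[1] != "A") return("excluded")
  b_positions <- which(seq_ab == "B")
  if (length(b_positions) == 0) return("control")
  after_first_b <- seq_ab[-seq_len(b_positions[1])]
  if (length(after_first_b) == 0) return("control")
  if (sum(after_first_b == "B") / length(after_first_b) >= threshold) "case"
  else "control"
}

# every A/B sequence of a given length
all_sequences <- function(len) {
  grid <- expand.grid(rep(list(c("A", "B")), len), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, ], use.names = FALSE))
}

# prescriptions tibble from a list of per-person fill sequences
rx_from_sequences <- function(seqs, pair = drug_pair()) {
  atc <- c(A = pair$drug_a, B = pair$drug_b)
  dplyr::bind_rows(lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    tibble::tibble(person_id = sprintf("S%04d", i),
                   date = as.Date("2010-01-01") + 30 * (seq_along(s) - 1),
                   atc_code = atc[s])
  }))
}

# independent exact Hardy-Weinberg p by direct enumeration of genotype
# configurations with the observed allele count (probability proportional to
# the multinomial coefficient times 2^heterozygotes)
brute_force_hwe_midp <- function(n_het, n_hom_alt, n_total) {
  n_alt <- n_het + 2 * n_hom_alt
  hom_alt <- 0:(n_alt %/% 2)
  het <- n_alt - 2 * hom_alt
  keep <- het + hom_alt <= n_total
  het <- het[keep]; hom_alt <- hom_alt[keep]
  w <- mapply(function(h, ha) {
    exp(lgamma(n_total + 1) - lgamma(h + 1) - lgamma(ha + 1) -
          lgamma(n_total - h - ha + 1) + h * log(2))
  }, het, hom_alt)
  p <- w / sum(w)
  obs <- p[het == n_het & hom_alt == n_hom_alt]
  sum(p[p < obs - 1e-12]) + 0.5 * sum(p[abs(p - obs) <= 1e-12])
}
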