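# fixtures built in code, shared across test files

# balanced paired vectors with known structure
make_paired <- function(n_persons, effect = 0, sd_person = 1, sd_error = 0.5,
                        seed = 1) {
  set.seed(seed)
  person <- rep(paste0("p", seq_len(n_persons)), each = 2)
  tissue <- rep(c("tumor", "normal"), n_persons)
  y <- rnorm(n_persons, 0, sd_person)[rep(seq_len(n_persons), each = 2)] +
    ifelse(tissue == "tumor", effect, 0) +
    rnorm(2 * n_persons, 0, sd_error)
  list(y = y, tissue = tissue, person = person)
}

# independently coded textbook chi-square on the category-vs-rest 2x2 table
chisq_oracle <- function(k_sig, n_sig, k_chip, n_chip, correct = FALSE) {
  o <- c(k_sig, n_sig - k_sig, k_chip, n_chip - k_chip)
  rs <- c(n_sig, n_chip)
  cs <- c(k_sig + k_chip, n_sig - k_sig + n_chip - k_chip)
  N <- n_sig + n_chip
  e <- c(rs[1] * cs[1], rs[1] * cs[2], rs[2] * cs[1], rs[2] * cs[2]) / N
  dev <- abs(o - e)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / e)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

# three differential-pathway lists arranged to the published intersection
# structure: |UC|=53, |carcinoma-in-colitis|=61, |sporadic|=59, triple
# intersection 29, UC&colitis-only 14, sporadic&UC-only 0
make_published_venn_lists <- function() {
  id <- function(prefix, n) if (n > 0) paste0(prefix, seq_len(n)) else character(0)
  triple <- id("t", 29)
  uc_cc  <- id("uc_cc", 14)     # UC & colitis carcinoma only
  uc_only <- id("uc", 53 - 29 - 14)
  cc_sp  <- id("cc_sp", 10)     # colitis & sporadic only (not printed; free)
  cc_only <- id("cc", 61 - 29 - 14 - 10)
  sp_only <- id("sp", 59 - 29 - 10)
  as_list <- function(ids, dir = "down") {
    structure(data.frame(pathway = ids, fc = -2.5, q = 0.01, direction = dir,
                         stringsAsFactors = FALSE),
              class = c("diff_pathway_list", "data.frame"))
  }
  list(
    UC = as_list(c(triple, uc_cc, uc_only)),
    UC_CRC = as_list(c(triple, uc_cc, cc_sp, cc_only)),
    sporadic_CRC = as_list(c(triple, cc_sp, sp_only))
  )
}
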