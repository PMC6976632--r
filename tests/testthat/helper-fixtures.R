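# Shared fixtures, built in code at test time.

# a tiny hand-checkable proteome: positions of K/Y/S/T are known
tiny_proteome <- function() {
  proteome(accession = c("P1", "P2", "P3"),
           sequence = c("MKKY",              # K at 2,3; Y at 4
                        "KAKYK",             # K at 1,3,5; Y at 4
                        "KKKYSSTA"),         # K 1:3, Y 4, S 5:6, T 7
           description = c("60S ribosomal protein L1",
                           "39S mitochondrial ribosomal protein L2",
                           "hypothetical protein 3"))
}

# IDR sets for the tiny proteome: P1 [2,3], P2 [1,2], P3 [3,5]
tiny_idrsets <- function(caller = "VSL2b") {
  list(P1 = idr_set("P1", 2, 3, 4, caller),
       P2 = idr_set("P2", 1, 2, 5, caller),
       P3 = idr_set("P3", 3, 5, 8, caller))
}

tiny_registry <- function() {
  load_study_registry(data.frame(study_id = c("SK", "SY"),
                                 target_residue = c("K", "Y"),
                                 chemistry = c("BirA", "APEX2")))
}

make_sites <- function(study_id, accession, position, residue,
                       modification = "biotin") {
  data.frame(study_id = study_id, accession = accession,
             position = position, residue = residue,
             modification = modification, stringsAsFactors = FALSE)
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# random normalized IDR set on a protein of length L
random_idr_set <- function(L, max_intervals = 6, accession = "R",
                           caller = "rand") {
  n <- sample.int(max_intervals, 1L) - 1L
  if (n == 0L) return(idr_set(accession, length = L, caller = caller))
  s <- sort(sample.int(L, n, replace = TRUE))
  e <- pmin(L, s + sample.int(8, n, replace = TRUE) - 1L)
  idr_set(accession, s, e, L, caller)
}

# brute-force binomial tail oracle: naive pmf products, no log tricks
binom_oracle <- function(k, n, p0, alternative) {
  pmf <- vapply(0:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i),
                numeric(1))
  if (alternative == "greater") sum(pmf[(k:n) + 1L])
  else sum(pmf[pmf <= pmf[[k + 1L]] * (1 + 1e-7)])
}

# brute-force Wallenius pmf by enumeration over ordered draw sequences:
# sum over all subsets of draw slots assigned to category items
wallenius_enum_pmf <- function(x, m1, m2, n, odds) {
  if (x < max(0, n - m2) || x > min(n, m1)) return(0)
  slots <- if (x == 0L) matrix(integer(0), nrow = 0L)
           else utils::combn(n, x)
  seq_prob <- function(white_slots) {
    wrem <- m1; brem <- m2; p <- 1
    for (j in seq_len(n)) {
      tot <- odds * wrem + brem
      if (j %in% white_slots) {
        p <- p * odds * wrem / tot; wrem <- wrem - 1L
      } else {
        p <- p * brem / tot; brem <- brem - 1L
      }
    }
    p
  }
  if (x == 0L) return(seq_prob(integer(0)))
  sum(apply(slots, 2L, seq_prob))
}
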