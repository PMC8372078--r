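# Shared fixtures, all built in code.

# one sire, two dams; dam d1 has two daughters (full sisters), dam d2 one
# (their paternal half-sister)
sibPedigree <- function() {
  buildPedigree(data.frame(
    id = c("s", "d1", "d2", "g1", "g2", "h1"),
    sex = c("M", "F", "F", "F", "F", "F"),
    dam = c(NA, NA, NA, "d1", "d1", "d2"),
    sire = c(NA, NA, NA, "s", "s", "s")))
}

# random valid haplodiploid pedigree of about n individuals
randomPedigree <- function(n, seed) {
  set.seed(seed)
  n_found <- max(4L, n %/% 3L)
  sex <- c(rep(c("F", "M"), length.out = n_found),
           sample(c("F", "M"), n - n_found, replace = TRUE))
  id <- sprintf("i%02d", seq_len(n))
  dam <- rep(NA_character_, n)
  sire <- rep(NA_character_, n)
  for (k in (n_found + 1L):n) {
    prev_f <- id[which(sex[seq_len(k - 1L)] == "F")]
    prev_m <- id[which(sex[seq_len(k - 1L)] == "M")]
    dam[k] <- sample(prev_f, 1)
    if (sex[k] == "F" && length(prev_m)) sire[k] <- sample(prev_m, 1)
  }
  buildPedigree(data.frame(id = id, sex = sex, dam = dam, sire = sire))
}

smallHalfsibDesign <- function(n_sires = 12L)
  halfsibDesign(n_sires = n_sires,
                dams_per_sire = c("1" = n_sires %/% 3L,
                                  "2" = n_sires %/% 3L,
                                  "3" = n_sires - 2L * (n_sires %/% 3L)))

fastModelConfig <- function(seed = 1L)
  thresholdModelConfig(n_samples = 4000L, burn_in = 1000L, thin = 4L,
                       seed = seed)
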