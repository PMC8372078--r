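# Haplodiploid pedigrees and additive relatedness.
#
# Transmission rules: a daughter receives her sire's entire haploid genome
# plus one maternal gamete; a son receives one maternal gamete only (he has
# no sire). Coancestry f(i,j) is the probability that one allele drawn at
# random from i and one from j are identical by descent (a haploid male
# carries a single allele, so a draw from him is deterministic). The
# additive relationship is a = 2 f throughout, for females and males alike;
# only diploid females are ever phenotyped, so the male diagonal convention
# (a_mm = 2) never enters a likelihood -- males act as transmission links.

normalizeSex <- function(sex) {
  s <- toupper(substr(trimws(as.character(sex)), 1, 1))
  out <- ifelse(s %in% c("F", "2"), "F", ifelse(s %in% c("M", "1"), "M", NA))
  if (anyNA(out)) stop("sex must be coded female/male (F/M)", call. = FALSE)
  out
}

#' Build and validate a haplodiploid pedigree
#'
#' Checks ids, sexes and parent links, rejects males with a sire and any
#' ancestry cycle, and returns the records topologically sorted (parents
#' before offspring). Empty/`NA` parents are unknown and act as unique
#' unrelated founders.
#'
#' @param records data.frame with columns `id`, `sex`, `dam`, `sire`
#'   (character or coercible; empty string or `NA` = unknown).
#' @param strict enforce haplodiploid sex rules (males sireless, sires
#'   male). `strict = FALSE` permits all-female two-parent pedigrees, in
#'   which the relatedness recursion reduces to the standard diploid
#'   tabular method -- useful for cross-validation, not for real wasp
#'   pedigrees.
#' @return a [HaploPedigree-class].
#' @examples
#' ped <- buildPedigree(data.frame(
#'   id = c("s1", "d1", "x1"), sex = c("M", "F", "F"),
#'   dam = c(NA, NA, "d1"), sire = c(NA, NA, "s1")))
#' pedIds(ped)
#' @export
buildPedigree <- function(records, strict = TRUE) {
  stopifnot(is.data.frame(records),
            all(c("id", "sex", "dam", "sire") %in% names(records)))
  p <- data.frame(id = as.character(records$id),
                  sex = normalizeSex(records$sex),
                  dam = as.character(records$dam),
                  sire = as.character(records$sire),
                  stringsAsFactors = FALSE)
  p$dam[!is.na(p$dam) & p$dam == ""] <- NA
  p$sire[!is.na(p$sire) & p$sire == ""] <- NA
  if (anyDuplicated(p$id)) {
    stop("duplicate ids: ", paste(unique(p$id[duplicated(p$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- strict & p$sex == "M" & !is.na(p$sire)
  if (any(bad)) {
    stop("males cannot have a sire (unfertilized eggs): ",
         paste(p$id[bad], collapse = ", "), call. = FALSE)
  }
  for (col in c("dam", "sire")) {
    miss <- !is.na(p[[col]]) & !(p[[col]] %in% p$id)
    if (any(miss)) {
      stop("unknown ", col, " id(s): ",
           paste(unique(p[[col]][miss]), collapse = ", "), call. = FALSE)
    }
  }
  if (any(!is.na(p$dam) & p$sex[match(p$dam, p$id)] != "F", na.rm = TRUE)) {
    stop("a dam must be female", call. = FALSE)
  }
  if (strict &&
      any(!is.na(p$sire) & p$sex[match(p$sire, p$id)] != "M", na.rm = TRUE)) {
    stop("a sire must be male", call. = FALSE)
  }
  # Kahn topological sort; leftovers indicate a cycle (incl. self-parents)
  n <- nrow(p)
  di <- match(p$dam, p$id); si <- match(p$sire, p$id)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (pa in c(di[i], si[i])) {
      if (!is.na(pa)) {
        if (pa == i) stop("individual '", p$id[i], "' is its own parent",
                          call. = FALSE)
        indeg[i] <- indeg[i] + 1L
        kids[[pa]] <- c(kids[[pa]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    order <- c(order, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(order) != n) {
    stop("pedigree contains a cycle involving: ",
         paste(p$id[setdiff(seq_len(n), order)], collapse = ", "),
         call. = FALSE)
  }
  new("HaploPedigree", ped = p[order, , drop = FALSE])
}

#' Haplodiploid additive relationship matrix
#'
#' Recursive (tabular) construction of a = 2 x coancestry under
#' haplodiploid transmission. Processing individuals in pedigree order,
#' with f the coancestry and d, s the dam and sire (unknown parents
#' contribute nothing):
#' females: f(i, j) = (f(d, j) + f(s, j)) / 2, f(i, i) = (1 + f(d, s)) / 2;
#' males:   f(i, j) = f(d, j),                f(i, i) = 1.
#' Inbreeding is handled by the recursion (a non-inbred female has diagonal
#' 1, a haploid male diagonal 2).
#'
#' @param ped a [HaploPedigree-class].
#' @return a [RelatednessMatrix-class] over all pedigree ids.
#' @examples
#' ped <- buildPedigree(data.frame(
#'   id = c("s", "d", "g1", "g2"), sex = c("M", "F", "F", "F"),
#'   dam = c(NA, NA, "d", "d"), sire = c(NA, NA, "s", "s")))
#' relatedness(haplodiploidAmatrix(ped))["g1", "g2"] # full sisters: 0.75
#' @export
haplodiploidAmatrix <- function(ped) {
  stopifnot(is(ped, "HaploPedigree"))
  p <- ped@ped
  n <- nrow(p)
  di <- match(p$dam, p$id); si <- match(p$sire, p$id)
  f <- matrix(0, n, n)
  for (i in seq_len(n)) {
    prev <- seq_len(i - 1L)
    if (p$sex[i] == "F") {
      fd <- if (!is.na(di[i])) f[di[i], prev] else rep(0, i - 1L)
      fs <- if (!is.na(si[i])) f[si[i], prev] else rep(0, i - 1L)
      if (i > 1L) {
        f[i, prev] <- (fd + fs) / 2
        f[prev, i] <- f[i, prev]
      }
      fds <- if (!is.na(di[i]) && !is.na(si[i])) f[di[i], si[i]] else 0
      f[i, i] <- (1 + fds) / 2
    } else {
      if (i > 1L) {
        f[i, prev] <- if (!is.na(di[i])) f[di[i], prev] else rep(0, i - 1L)
        f[prev, i] <- f[i, prev]
      }
      f[i, i] <- 1
    }
  }
  a <- 2 * f
  dimnames(a) <- list(p$id, p$id)
  new("RelatednessMatrix", entries = a)
}

#' Gene-dropping estimate of coancestry
#'
#' Independent Monte-Carlo oracle for [haplodiploidAmatrix()]: founder
#' alleles get unique labels, alleles are dropped through the pedigree under
#' haplodiploid transmission (daughters: sire's allele + one random maternal
#' allele; sons: one random maternal allele), and coancestry is estimated as
#' the identity-by-descent probability of one random allele from each
#' individual (exact within-replicate expectation over the draw).
#'
#' @param ped a [HaploPedigree-class].
#' @param i,j individual ids (i == j gives self-coancestry).
#' @param n_reps number of replicate drops (>= 1).
#' @param seed integer seed.
#' @return list with `coancestry`, `a` (= 2 x coancestry), `se` (Monte-Carlo
#'   standard error of `a`) and `n_reps`.
#' @export
geneDropCoancestry <- function(ped, i, j, n_reps = 2e5, seed = 1) {
  stopifnot(is(ped, "HaploPedigree"), n_reps >= 1)
  per <- geneDropPairs(ped, cbind(i, j), n_reps = n_reps, seed = seed,
                       per_rep = TRUE)[[1]]
  est <- mean(per)
  list(coancestry = est, a = 2 * est,
       se = 2 * sd(per) / sqrt(n_reps), n_reps = as.integer(n_reps))
}

# Drop alleles once for all replicates and score many pairs at once.
# Returns a list of per-replicate IBD probabilities (per_rep = TRUE) or of
# scalar estimates.
geneDropPairs <- function(ped, pairs, n_reps = 2e5, seed = 1,
                          per_rep = FALSE) {
  p <- ped@ped
  n <- nrow(p)
  di <- match(p$dam, p$id); si <- match(p$sire, p$id)
  set.seed(seed)
  # allele label matrices: females n_reps x 2, males n_reps x 1
  alle <- vector("list", n)
  lab <- 0L
  for (k in seq_len(n)) {
    if (is.na(di[k])) {
      mg <- matrix(lab + 1L, n_reps, 1); lab <- lab + 1L
      if (p$sex[k] == "F" && is.na(si[k])) {
        # unknown-dam female founder: second allele also unique
        mg <- cbind(mg, lab + 1L); lab <- lab + 1L
      }
      maternal <- mg
    } else {
      d <- alle[[di[k]]]
      pick <- runif(n_reps) < 0.5
      maternal <- matrix(ifelse(pick, d[, 1], d[, 2]), n_reps, 1)
    }
    if (p$sex[k] == "M") {
      alle[[k]] <- maternal[, 1, drop = FALSE]
    } else {
      if (is.na(si[k])) {
        if (is.na(di[k])) {
          alle[[k]] <- maternal            # both unknown: two fresh labels
        } else {
          pat <- matrix(lab + 1L, n_reps, 1); lab <- lab + 1L
          alle[[k]] <- cbind(pat, maternal)
        }
      } else {
        sa <- alle[[si[k]]]
        if (ncol(sa) == 1L) {        # haploid sire transmits his one allele
          pat <- sa
        } else {                     # diploid "sire" (non-strict pedigree)
          pick <- runif(n_reps) < 0.5
          pat <- matrix(ifelse(pick, sa[, 1], sa[, 2]), n_reps, 1)
        }
        alle[[k]] <- cbind(pat, maternal)
      }
    }
  }
  idx <- function(id) {
    k <- match(as.character(id), p$id)
    if (is.na(k)) stop("id '", id, "' not in pedigree", call. = FALSE)
    k
  }
  out <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    a <- alle[[idx(pairs[r, 1])]]
    b <- alle[[idx(pairs[r, 2])]]
    # expected IBD indicator for one random draw from each individual
    tot <- matrix(0, n_reps, 1)
    for (ca in seq_len(ncol(a))) for (cb in seq_len(ncol(b))) {
      tot <- tot + (a[, ca] == b[, cb])
    }
    per <- as.numeric(tot) / (ncol(a) * ncol(b))
    out[[r]] <- if (per_rep) per else mean(per)
  }
  out
}

#' Principal submatrix over phenotyped individuals
#'
#' @param A a [RelatednessMatrix-class].
#' @param ids ids to keep, in the requested order.
#' @return a [RelatednessMatrix-class] over `ids`.
#' @export
phenotypedSubmatrix <- function(A, ids) {
  stopifnot(is(A, "RelatednessMatrix"))
  ids <- as.character(ids)
  miss <- setdiff(ids, rownames(A@entries))
  if (length(miss)) {
    stop("ids not in relatedness matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  new("RelatednessMatrix", entries = A@entries[ids, ids, drop = FALSE])
}
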