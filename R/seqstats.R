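# Universal genetic code, codon -> amino acid (one-letter, "*" for stop),
# taken from Biostrings. Codons use T, not U.
genetic_code_table <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code) <- gsub("U", "T", names(code))
  code
}

.pb_cache <- new.env(parent = emptyenv())

# Per-codon fractional synonymous site count (NG86): for each of the three
# positions, the fraction of the three possible single-base changes that are
# synonymous. Changes to stop codons count as nonsynonymous, keeping
# S + N = 3 per codon.
syn_sites_by_codon <- function() {
  if (!is.null(.pb_cache$syn_sites)) return(.pb_cache$syn_sites)
  code <- genetic_code_table()
  bases <- c("A", "C", "G", "T")
  sense <- names(code)[code != "*"]
  s <- vapply(sense, function(codon) {
    aa <- code[[codon]]
    total <- 0
    for (pos in 1:3) {
      old <- substr(codon, pos, pos)
      for (b in setdiff(bases, old)) {
        alt <- codon
        substr(alt, pos, pos) <- b
        if (code[[alt]] == aa) total <- total + 1 / 3
      }
    }
    total
  }, numeric(1))
  .pb_cache$syn_sites <- s
  s
}

# Syn/nonsyn difference counts for one codon pair, averaged over all
# single-step mutational pathways; pathways passing through stop codons are
# excluded (if every pathway is blocked, all are used, which cannot occur for
# sense-codon pairs differing at <= 3 positions under the universal code but
# is kept as a guard).
codon_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- paste(sort(c(c1, c2)), collapse = "|")
  if (is.null(.pb_cache$pair_diffs)) .pb_cache$pair_diffs <- new.env(parent = emptyenv())
  hit <- .pb_cache$pair_diffs[[key]]
  if (!is.null(hit)) return(hit)
  code <- genetic_code_table()
  pos_diff <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  perms <- permutations_of(pos_diff)
  path_sd <- numeric(0)
  path_nd <- numeric(0)
  for (ord in perms) {
    cur <- c1
    sd <- 0; nd <- 0
    blocked <- FALSE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (code[[nxt]] == "*") { blocked <- TRUE; break }
      if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (!blocked) {
      path_sd <- c(path_sd, sd)
      path_nd <- c(path_nd, nd)
    }
  }
  if (!length(path_sd)) {
    # all pathways blocked: fall back to counting through stops
    for (ord in perms) {
      cur <- c1
      sd <- 0; nd <- 0
      for (pos in ord) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(c2, pos, pos)
        if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      path_sd <- c(path_sd, sd)
      path_nd <- c(path_nd, nd)
    }
  }
  out <- c(sd = mean(path_sd), nd = mean(path_nd))
  .pb_cache$pair_diffs[[key]] <- out
  out
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0) stop("sequence length is not a multiple of 3", call. = FALSE)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Per-codon NG86 components for a pair of codon vectors. Codons that are not
# plain sense ACGT triplets in either sequence (gaps, ambiguity codes, stops)
# are excluded pairwise: their rows carry zeros and ok = FALSE.
ng86_components <- function(cod1, cod2) {
  if (length(cod1) != length(cod2)) stop("sequences differ in length", call. = FALSE)
  syn_sites <- syn_sites_by_codon()
  L <- length(cod1)
  s1 <- numeric(L); s2 <- numeric(L)
  sd <- numeric(L); nd <- numeric(L)
  ok <- logical(L)
  sense <- names(syn_sites)
  for (i in seq_len(L)) {
    a <- toupper(cod1[i]); b <- toupper(cod2[i])
    if (!(a %in% sense) || !(b %in% sense)) next
    ok[i] <- TRUE
    s1[i] <- syn_sites[[a]]
    s2[i] <- syn_sites[[b]]
    if (a != b) {
      d <- codon_pair_diffs(a, b)
      sd[i] <- d[["sd"]]
      nd[i] <- d[["nd"]]
    }
  }
  list(s1 = s1, s2 = s2, sd = sd, nd = nd, ok = ok)
}

#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) log(1 - 4 p / 3)`; undefined (`NA`) for `p >= 3/4`.
#'
#' @param p Proportion of differences per site.
#' @return Corrected distance(s).
#' @export
jc_correct <- function(p) {
  ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Nei-Gojobori (1986) pairwise dN/dS components
#'
#' Counts synonymous and nonsynonymous sites by the fractional-site method
#' (averaged over the two sequences) and differences by averaging over all
#' orderings of single-step mutational pathways between differing codons,
#' excluding pathways through stop codons. Proportions are Jukes-Cantor
#' corrected. Codons containing gaps or ambiguity characters in either
#' sequence are excluded pairwise.
#'
#' @param seq_a,seq_b Aligned coding sequences (nucleotide strings of equal
#'   length, multiple of 3) or character vectors of codons.
#' @return A list: `N_sites`, `S_sites`, `N_diffs`, `S_diffs`, `pN`, `pS`,
#'   `dN`, `dS`, and `n_codons` (codons compared after exclusion).
#' @examples
#' ng86_pair("TTT", "TTC")  # one synonymous difference
#' @export
ng86_pair <- function(seq_a, seq_b) {
  cod1 <- if (length(seq_a) == 1L) split_codons(seq_a) else seq_a
  cod2 <- if (length(seq_b) == 1L) split_codons(seq_b) else seq_b
  comp <- ng86_components(cod1, cod2)
  if (!any(comp$ok)) stop("no comparable codons after exclusion", call. = FALSE)
  S <- sum((comp$s1 + comp$s2)[comp$ok]) / 2
  n_cod <- sum(comp$ok)
  N <- 3 * n_cod - S
  Sd <- sum(comp$sd)
  Nd <- sum(comp$nd)
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  list(N_sites = N, S_sites = S, N_diffs = Nd, S_diffs = Sd,
       pN = pN, pS = pS, dN = jc_correct(pN), dS = jc_correct(pS),
       n_codons = n_cod)
}

#' Pairwise dN and dS matrices over a codon alignment
#'
#' @param alignment Named character vector of aligned coding sequences
#'   (equal length, multiple of 3).
#' @return A list of two symmetric matrices `dN` and `dS` with zero
#'   diagonals; `NA` where the Jukes-Cantor correction is undefined.
#' @export
dnds_matrix <- function(alignment) {
  n <- length(alignment)
  if (n < 2L) stop("need at least 2 alleles", call. = FALSE)
  nm <- names(alignment)
  dN <- matrix(0, n, n, dimnames = list(nm, nm))
  dS <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- ng86_pair(alignment[[i]], alignment[[j]])
      dN[i, j] <- dN[j, i] <- p$dN
      dS[i, j] <- dS[j, i] <- p$dS
    }
  }
  list(dN = dN, dS = dS)
}

# Precompute per-pair per-codon NG86 components for an alignment; used by the
# window and domain statistics so each codon pair is evaluated once.
alignment_components <- function(alignment) {
  n <- length(alignment)
  if (n < 2L) stop("need at least 2 alleles", call. = FALSE)
  cods <- lapply(alignment, split_codons)
  L <- unique(lengths(cods))
  if (length(L) != 1L) stop("sequences differ in length", call. = FALSE)
  pairs <- utils::combn(n, 2L)
  comps <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    comps[[k]] <- ng86_components(cods[[pairs[1L, k]]], cods[[pairs[2L, k]]])
  }
  list(pairs = pairs, comps = comps, L = L)
}

# Mean dN, dS over pairs for a codon index range, from precomputed components.
range_rates <- function(ac, idx) {
  dN <- dS <- numeric(length(ac$comps))
  for (k in seq_along(ac$comps)) {
    cp <- ac$comps[[k]]
    ok <- cp$ok[idx]
    n_cod <- sum(ok)
    if (n_cod == 0L) { dN[k] <- dS[k] <- NA_real_; next }
    S <- sum((cp$s1[idx] + cp$s2[idx])[ok]) / 2
    N <- 3 * n_cod - S
    pS <- if (S > 0) sum(cp$sd[idx]) / S else NA_real_
    pN <- if (N > 0) sum(cp$nd[idx]) / N else NA_real_
    dS[k] <- jc_correct(pS)
    dN[k] <- jc_correct(pN)
  }
  mean_dN <- mean(dN, na.rm = TRUE)
  mean_dS <- mean(dS, na.rm = TRUE)
  c(dN = if (is.nan(mean_dN)) NA_real_ else mean_dN,
    dS = if (is.nan(mean_dS)) NA_real_ else mean_dS)
}

#' Sliding-window dN/dS along a codon alignment
#'
#' For each window of `size` codons (step `step`), per-pair dN and dS are
#' computed on the windowed codons and averaged over all unordered allele
#' pairs. The reported ratio is mean dN / mean dS, which stays defined when
#' individual pairs have zero synonymous differences; per-pair ratio
#' averaging is available via `ratio_method = "per_pair"`.
#'
#' @param alignment Named character vector of aligned coding sequences.
#' @param size Window size in codons.
#' @param step Window step in codons.
#' @param ratio_method `"mean_of_rates"` (default) or `"per_pair"`.
#' @return A data.frame with `start_codon`, `end_codon`, `dN`, `dS`,
#'   `dN_dS` (NA where mean dS is 0 or undefined).
#' @export
sliding_window_dnds <- function(alignment, size = 20L, step = 1L,
                                ratio_method = c("mean_of_rates", "per_pair")) {
  ratio_method <- match.arg(ratio_method)
  ac <- alignment_components(alignment)
  if (ac$L < size) stop("alignment shorter than the window size", call. = FALSE)
  starts <- seq(1L, ac$L - size + 1L, by = step)
  out <- data.frame(start_codon = starts, end_codon = starts + size - 1L,
                    dN = NA_real_, dS = NA_real_, dN_dS = NA_real_)
  for (w in seq_along(starts)) {
    idx <- starts[w]:(starts[w] + size - 1L)
    if (ratio_method == "mean_of_rates") {
      r <- range_rates(ac, idx)
      out$dN[w] <- r[["dN"]]
      out$dS[w] <- r[["dS"]]
      out$dN_dS[w] <- if (!is.na(r[["dS"]]) && r[["dS"]] > 0) r[["dN"]] / r[["dS"]] else NA_real_
    } else {
      ratios <- vapply(seq_along(ac$comps), function(k) {
        cp <- ac$comps[[k]]
        ok <- cp$ok[idx]
        if (!any(ok)) return(NA_real_)
        S <- sum((cp$s1[idx] + cp$s2[idx])[ok]) / 2
        N <- 3 * sum(ok) - S
        dS <- jc_correct(if (S > 0) sum(cp$sd[idx]) / S else NA_real_)
        dN <- jc_correct(if (N > 0) sum(cp$nd[idx]) / N else NA_real_)
        if (is.na(dS) || dS == 0) NA_real_ else dN / dS
      }, numeric(1))
      r <- range_rates(ac, idx)
      out$dN[w] <- r[["dN"]]
      out$dS[w] <- r[["dS"]]
      m <- mean(ratios, na.rm = TRUE)
      out$dN_dS[w] <- if (is.nan(m)) NA_real_ else m
    }
  }
  out
}

#' Per-domain average dN, dS and dN/dS
#'
#' Computes the pairwise-averaged statistics of [sliding_window_dnds()] over
#' each domain of a partition instead of a moving window.
#'
#' @param alignment Named character vector of aligned coding sequences; if
#'   `domains` is `NULL` the alignment's `domains` attribute is used.
#' @param domains Data.frame with columns `name`, `start_codon`, `end_codon`
#'   (1-based inclusive) covering `[1, L]` without overlap.
#' @return A data.frame with one row per domain: `name`, `start_codon`,
#'   `end_codon`, `dN`, `dS`, `dN_dS`.
#' @export
domain_dnds <- function(alignment, domains = NULL) {
  if (is.null(domains)) domains <- attr(alignment, "domains")
  if (is.null(domains)) stop("no domain partition supplied", call. = FALSE)
  need <- c("name", "start_codon", "end_codon")
  if (!all(need %in% names(domains))) {
    stop("domains need columns name, start_codon, end_codon", call. = FALSE)
  }
  ac <- alignment_components(alignment)
  d <- domains[order(domains$start_codon), , drop = FALSE]
  if (any(d$end_codon < d$start_codon)) stop("zero-length domain", call. = FALSE)
  if (d$start_codon[1L] != 1L || d$end_codon[nrow(d)] != ac$L ||
      (nrow(d) > 1L && any(d$start_codon[-1L] != d$end_codon[-nrow(d)] + 1L))) {
    stop("domain partition must cover the alignment without gaps or overlap",
         call. = FALSE)
  }
  out <- data.frame(name = d$name, start_codon = d$start_codon,
                    end_codon = d$end_codon, dN = NA_real_, dS = NA_real_,
                    dN_dS = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(d))) {
    r <- range_rates(ac, d$start_codon[k]:d$end_codon[k])
    out$dN[k] <- r[["dN"]]
    out$dS[k] <- r[["dS"]]
    out$dN_dS[k] <- if (!is.na(r[["dS"]]) && r[["dS"]] > 0) r[["dN"]] / r[["dS"]] else NA_real_
  }
  out
}
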