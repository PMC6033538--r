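## k-mer enrichment stand-in for de novo motif discovery: observed k-mer
## counts in site windows vs a dinucleotide-preserving shuffle null.

.ALPHABET <- c("A", "C", "G", "U")

## Altschul-Erickson dinucleotide-preserving shuffle of one sequence.
## Builds the dinucleotide transition multigraph and walks a random Eulerian
## path from the first to the last character.
.dinuc_shuffle <- function(chars) {
  n <- length(chars)
  if (n <= 3L) return(chars)
  verts <- unique(chars)
  edges <- split(chars[-1L], factor(chars[-n], levels = verts))
  last <- chars[n]
  repeat {
    ## pick a random candidate "last edge" per non-terminal vertex, then
    ## accept iff following them from every vertex reaches the terminal
    last_edge <- vapply(verts, function(v) {
      if (v == last) NA_character_
      else { e <- edges[[v]]; e[sample.int(length(e), 1L)] }
    }, character(1L))
    ok <- TRUE
    for (v in verts) {
      if (v == last) next
      seen <- character(0); cur <- v
      while (cur != last) {
        if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur); cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  ## shuffle the remaining edges, append the reserved last edge
  out_edges <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (!is.na(last_edge[[v]])) {
      drop <- match(last_edge[[v]], e)
      e <- e[-drop]
    }
    e <- if (length(e)) e[sample.int(length(e))] else character(0)
    c(e, if (!is.na(last_edge[[v]])) last_edge[[v]])
  })
  names(out_edges) <- verts
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  res <- character(n); res[1L] <- chars[1L]; cur <- chars[1L]
  for (i in 2:n) {
    nxt <- out_edges[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    res[i] <- nxt; cur <- nxt
  }
  res
}

## total k-mer counts over a list of character vectors, as a named integer
## vector over all 4^k codes (integer encoding, vectorised rolling code)
.count_kmers <- function(char_list, k) {
  pow <- 4L^((k - 1L):0L)
  counts <- numeric(4L^k)
  for (chars in char_list) {
    v <- match(chars, .ALPHABET) - 1L
    n <- length(v)
    if (n < k || anyNA(v)) next
    em <- stats::embed(v, k)[, k:1L, drop = FALSE]   # rows = windows, 5'->3'
    code <- as.vector(em %*% pow) + 1L
    tb <- tabulate(code, nbins = 4L^k)
    counts <- counts + tb
  }
  counts
}

.decode_kmer <- function(code, k) {
  v <- integer(k); x <- code - 1L
  for (i in k:1L) { v[i] <- x %% 4L; x <- x %/% 4L }
  paste(.ALPHABET[v + 1L], collapse = "")
}

#' k-mer enrichment in site windows against a dinucleotide-shuffle null
#'
#' Counts all k-mers in a set of equal-length sequence windows (e.g. 30-nt
#' windows centered on binding sites) and compares each observed count with
#' its distribution over dinucleotide-preserving shuffles of the same
#' windows: `z = (obs - mean_shuffle) / sqrt(sd_shuffle^2 + mean_shuffle + 1)`.
#' The unit pseudo-variance regularizes the denominator: with 4^k possible
#' k-mers most shuffle counts are zero, and an unregularized z would be
#' unbounded for any k-mer observed once but absent from the shuffles.
#' Windows shorter than `k` are excluded with a warning.  Sequences may use T or U; T is mapped
#' to U.
#'
#' @param windows character vector of sequence windows.
#' @param k k-mer length (default 8).
#' @param n_shuffle number of shuffle rounds (>= 100 recommended; minimum 2).
#' @param seed integer seed for the shuffle RNG.
#' @return data.frame sorted by `z` descending: `kmer`, `observed`,
#'   `mean_shuffle`, `sd_shuffle`, `z`.  Only k-mers observed at least once
#'   in the real windows are reported.
#' @export
kmer_enrichment <- function(windows, k = 8L, n_shuffle = 100L, seed = 1L) {
  if (n_shuffle < 2L) stop_("n_shuffle must be >= 2")
  windows <- toupper(windows)
  windows <- chartr("T", "U", windows)
  short <- nchar(windows) < k
  if (any(short)) {
    warning(sprintf("%d window(s) shorter than k = %d excluded", sum(short), k))
    windows <- windows[!short]
  }
  if (length(windows) == 0L) stop_("no usable windows")
  char_list <- strsplit(windows, "", fixed = TRUE)
  obs <- .count_kmers(char_list, k)

  set.seed(seed)
  sum1 <- numeric(length(obs)); sum2 <- numeric(length(obs))
  for (b in seq_len(n_shuffle)) {
    cnt <- .count_kmers(lapply(char_list, .dinuc_shuffle), k)
    sum1 <- sum1 + cnt; sum2 <- sum2 + cnt^2
  }
  mu <- sum1 / n_shuffle
  sd <- sqrt(pmax(0, sum2 / n_shuffle - mu^2) * n_shuffle / (n_shuffle - 1))
  keep <- which(obs > 0)
  z <- (obs[keep] - mu[keep]) / sqrt(sd[keep]^2 + mu[keep] + 1)
  out <- data.frame(kmer = vapply(keep, .decode_kmer, character(1L), k = k),
                    observed = obs[keep], mean_shuffle = mu[keep],
                    sd_shuffle = sd[keep], z = z)
  out <- out[order(-out$z, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out
}
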