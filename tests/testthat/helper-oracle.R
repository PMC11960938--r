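# Independent brute-force alignment oracle: enumerates every monotone
# alignment path (moves D = substitution, X = gap in b, Y = gap in a) and
# scores each completed path directly from the cost model, with no dynamic
# programming.  Only feasible for short sequences.

oracle_overlap_score <- function(a, b, params = scoring_params()) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  sm <- params$substitution_matrix
  go <- params$gap_open; ge <- params$gap_extend
  free <- params$free_end_gaps
  best <- -Inf

  score_path <- function(moves) {
    # positions of a/b consumed before each alignment column
    di <- cumsum(moves != 3L)   # i after each column
    dj <- cumsum(moves != 2L)   # j after each column
    s <- 0
    subs <- moves == 1L
    if (any(subs)) {
      s <- sum(sm[cbind(av[di[subs]], bv[dj[subs]])])
    }
    r <- rle(moves)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      v <- r$values[k]
      if (v == 1L) next
      L <- r$lengths[k]
      if (v == 2L) {     # gap in b: free iff it touches an end of b
        j0 <- if (starts[k] == 1L) 0L else dj[starts[k] - 1L]
        j1 <- dj[ends[k]]
        is_free <- free && (j0 == 0L || j1 == m)
      } else {           # gap in a
        i0 <- if (starts[k] == 1L) 0L else di[starts[k] - 1L]
        i1 <- di[ends[k]]
        is_free <- free && (i0 == 0L || i1 == n)
      }
      if (!is_free) s <- s - (go + ge * L)
    }
    s
  }

  moves <- integer(n + m)
  recurse <- function(i, j, depth) {
    if (i == n && j == m) {
      s <- score_path(moves[seq_len(depth)])
      if (s > best) best <<- s
      return(invisible())
    }
    if (i < n && j < m) {
      moves[depth + 1L] <<- 1L; recurse(i + 1L, j + 1L, depth + 1L)
    }
    if (i < n) { moves[depth + 1L] <<- 2L; recurse(i + 1L, j, depth + 1L) }
    if (j < m) { moves[depth + 1L] <<- 3L; recurse(i, j + 1L, depth + 1L) }
  }
  recurse(0L, 0L, 0L)
  best
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# naive per-cell window summation for the dot-plot oracle
oracle_dotplot <- function(seq, window, params = scoring_params()) {
  sm <- params$substitution_matrix
  v <- strsplit(seq, "")[[1]]
  n <- length(v); h <- window %/% 2
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- 0
      for (k in -h:h) {
        if (i + k >= 1 && i + k <= n && j + k >= 1 && j + k <= n)
          s <- s + sm[v[i + k], v[j + k]]
      }
      out[i, j] <- s
    }
  }
  out
}

# mutate a DNA string at exactly k positions (distinct sites, substitutions)
mutate_k_sites <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  sites <- sample(length(chars), k)
  for (s in sites) {
    chars[s] <- sample(setdiff(c("A", "C", "G", "T"), chars[s]), 1)
  }
  paste(chars, collapse = "")
}
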