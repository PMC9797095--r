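# Shared fixtures, built once per test run and memoized.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- builder()
  fixture_env[[key]]
}

fx_duplex <- function() memo("duplex", function() build_aform("GCAU", duplex = TRUE))
fx_duplex_fit <- function() memo("duplex_fit", function() enm(fx_duplex()))
fx_toy3 <- function() memo("toy3", function() coarse_grain(build_aform("GAC")))
fx_hairpin <- function() memo("hairpin", function() build_hairpin("GCGCAGCGA", "GAAA"))

# finite-difference Hessian of a scalar energy function at x0
fd_hessian <- function(E, x0, h = 1e-5) {
  n <- length(x0)
  H <- matrix(0, n, n)
  for (i in 1:n) for (j in i:n) {
    pp <- x0; pp[i] <- pp[i] + h; pp[j] <- pp[j] + h
    pm <- x0; pm[i] <- pm[i] + h; pm[j] <- pm[j] - h
    mp <- x0; mp[i] <- mp[i] - h; mp[j] <- mp[j] + h
    mm <- x0; mm[i] <- mm[i] - h; mm[j] <- mm[j] - h
    H[i, j] <- H[j, i] <- (E(pp) - E(pm) - E(mp) + E(mm)) / (4 * h * h)
  }
  H
}

# brute-force enumeration of simple paths of a given edge length in an
# undirected graph, deduplicated under reversal
count_paths <- function(n, edges, len) {
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    adj[[edges[e, 1L]]] <- c(adj[[edges[e, 1L]]], edges[e, 2L])
    adj[[edges[e, 2L]]] <- c(adj[[edges[e, 2L]]], edges[e, 1L])
  }
  paths <- character()
  walk <- function(path) {
    if (length(path) == len + 1L) {
      rev_key <- paste(rev(path), collapse = "-")
      key <- paste(path, collapse = "-")
      paths <<- c(paths, min(key, rev_key))
      return()
    }
    for (nb in adj[[path[length(path)]]])
      if (!(nb %in% path)) walk(c(path, nb))
  }
  for (s in seq_len(n)) walk(s)
  length(unique(paths))
}

# exhaustive global alignment score by recursion (tiny sequences only)
brute_nw <- function(s, t) {
  a <- strsplit(s, "")[[1]]; b <- strsplit(t, "")[[1]]
  rec <- function(i, j) {
    if (i > length(a)) return(-(length(b) - j + 1L))
    if (j > length(b)) return(-(length(a) - i + 1L))
    max(rec(i + 1L, j + 1L) + if (a[i] == b[j]) 1L else -1L,
        rec(i + 1L, j) - 1L,
        rec(i, j + 1L) - 1L)
  }
  rec(1L, 1L)
}

# all set partitions of 1..n (n small)
all_partitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  out <- list()
  for (p in all_partitions(n - 1L)) {
    for (k in seq_along(p)) {
      q <- p; q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# delete atoms (by row index) from an rna_structure
drop_atoms <- function(x, rows) {
  keep <- setdiff(seq_len(nrow(x$atoms)), rows)
  at <- x$atoms[keep, , drop = FALSE]
  rownames(at) <- NULL
  rnaenm:::new_rna_structure(at, lapply(x$xyz, function(m)
    m[keep, , drop = FALSE]), x$source)
}

random_rotation_seeded <- function(seed) {
  set.seed(seed)
  rnaenm:::random_rotation()
}
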