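# Shared fixtures and independent oracles for the test suite.
# The fixture store is built once per test run into a session tempdir.

fx_env <- new.env(parent = emptyenv())

fx_store_dir <- function() {
  if (is.null(fx_env$dir)) {
    fx_env$dir <- file.path(tempdir(), "atomtrail-fixture-store")
    build_fixture_store(fx_env$dir)
  }
  fx_env$dir
}

fx_store <- function() {
  if (is.null(fx_env$store)) fx_env$store <- load_store(fx_store_dir())
  fx_env$store
}

fx_glycolysis_model <- function() {
  parse_model_csv(file.path(fx_store_dir(), "glycolysis_model.csv"))
}

fx_abc <- function() {
  if (is.null(fx_env$abc))
    fx_env$abc <- build_abc_model(fx_glycolysis_model(), fx_store())
  fx_env$abc
}

glycolysis_path <- c("HK", "PGI", "PFK", "ALDO", "TPI",
                     "GAPDH", "PGK", "PGM", "ENO", "PK")

# Apply an atom permutation to a molecule: atom at old index p[k] moves to
# new index k.
perm_mol <- function(m, p) {
  inv <- integer(length(p))
  inv[p] <- seq_along(p)
  b <- m$bonds
  if (nrow(b) > 0L) {
    b[, 1] <- inv[b[, 1]]
    b[, 2] <- inv[b[, 2]]
  }
  molecule(m$name, m$elements[p], b, m$charges[p])
}

# Structure-level certificate of the canonicalized molecule: identical
# across atom permutations iff the canonical order is isomorphism-invariant.
canon_cert <- function(m) {
  mc <- canonicalize(canonical_order(m))
  b <- mc$bonds
  paste(paste(mc$elements, mc$charges, collapse = ";"),
        paste(apply(b, 1, paste, collapse = "-"), collapse = ";"),
        sep = "#")
}

# All permutations of 1..n (n! rows).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- 1L
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out[r:(r + nrow(sub) - 1L), ] <- block
    r <- r + nrow(sub)
  }
  out
}

# Independent brute-force orbit oracle: enumerate all element/charge-class
# preserving vertex bijections, keep those that preserve the bond-order
# adjacency, and take the closure. Returns orbits as a sorted list of
# sorted integer vectors.
brute_force_orbits <- function(m) {
  n <- n_atoms(m)
  key <- paste(m$elements, m$charges)
  classes <- split(seq_len(n), key)
  adj <- matrix(0L, n, n)
  b <- m$bonds
  for (k in seq_len(nrow(b))) {
    adj[b[k, 1], b[k, 2]] <- b[k, 3]
    adj[b[k, 2], b[k, 1]] <- b[k, 3]
  }
  class_perms <- lapply(classes, function(idx) {
    if (length(idx) == 1L) return(matrix(idx))
    p <- all_perms(length(idx))
    matrix(idx[p], nrow = nrow(p))
  })
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  combos <- expand.grid(lapply(class_perms, function(p) seq_len(nrow(p))))
  for (g in seq_len(nrow(combos))) {
    perm <- integer(n)
    for (ci in seq_along(class_perms)) {
      perm[classes[[ci]]] <- class_perms[[ci]][combos[g, ci], ]
    }
    if (identical(adj[perm, perm], adj)) {
      for (i in seq_len(n)) {
        a <- find(i); bb <- find(perm[i])
        if (a != bb) parent[max(a, bb)] <- min(a, bb)
      }
    }
  }
  orbits <- unname(split(seq_len(n), vapply(seq_len(n), find, 0L)))
  orbits[order(vapply(orbits, min, 0L))]
}

orbit_key <- function(orbits) {
  paste(sort(vapply(orbits, function(o) paste(sort(o), collapse = ","), "")),
        collapse = "|")
}

# Deterministic sample of permutations (without replacement semantics not
# required; duplicates are harmless for invariance checking).
sample_perms <- function(n, k, seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(seq_len(k), function(i) sample.int(n))
}

entry_letters <- function(e, side) {
  unlist(strsplit(vapply(e[[side]], `[[`, "", "letters"), ""))
}

find_entry <- function(abc, name, variant = 1L) {
  hits <- Filter(function(e) e$name == name && e$variant == variant, abc$entries)
  if (length(hits) == 0L) stop("no such entry: ", name)
  hits[[1]]
}
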