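# Independent brute-force 1-persistence oracle: full simplex enumeration
# (dims 0-2) and naive boundary-matrix column reduction over Z/p.  Written
# against the textbook algorithm, deliberately sharing no code with the
# package's reduction engine.  Only usable for small clouds.

bruteForceH1 <- function(dm, maxScale, p = 2L) {
  n <- nrow(dm)
  simp <- list()
  for (i in seq_len(n))
    simp[[length(simp) + 1L]] <- list(v = i, val = 0, dim = 0L)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (dm[i, j] <= maxScale)
      simp[[length(simp) + 1L]] <- list(v = c(i, j), val = dm[i, j], dim = 1L)
  }
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n) {
      val <- max(dm[i, j], dm[i, k], dm[j, k])
      if (val <= maxScale && dm[i, j] <= maxScale && dm[i, k] <= maxScale &&
          dm[j, k] <= maxScale)
        simp[[length(simp) + 1L]] <- list(v = c(i, j, k), val = val, dim = 2L)
    }
  }
  # filtration order: value, then dimension, then lexicographic vertices
  keys <- vapply(simp, function(s)
    paste(sprintf("%.17e", s$val), s$dim,
          paste(sprintf("%04d", s$v), collapse = ""), sep = "|"), "")
  o <- order(vapply(simp, `[[`, numeric(1), "val"),
             vapply(simp, `[[`, integer(1), "dim"),
             keys)
  simp <- simp[o]
  ns <- length(simp)
  index <- new.env()
  for (s in seq_len(ns))
    assign(paste(simp[[s]]$v, collapse = ","), s, envir = index)

  # sparse columns: named integer vectors (row index -> coefficient)
  cols <- vector("list", ns)
  for (s in seq_len(ns)) {
    sx <- simp[[s]]
    if (sx$dim == 0L) { cols[[s]] <- integer(0); next }
    faces <- lapply(seq_along(sx$v), function(drop) sx$v[-drop])
    signs <- (-1L)^(seq_along(sx$v) + 1L)  # alternating +,-,+
    rows <- vapply(faces, function(f)
      get(paste(f, collapse = ","), envir = index), integer(1))
    coefs <- signs %% p
    keep <- coefs != 0L
    col <- coefs[keep]
    names(col) <- rows[keep]
    cols[[s]] <- col[order(as.integer(names(col)))]
  }

  low <- function(col) if (length(col) == 0L) 0L else
    max(as.integer(names(col)))
  addCol <- function(a, b, c) {
    # a + c*b mod p
    rows <- union(names(a), names(b))
    out <- integer(0)
    for (r in rows) {
      v <- ((if (r %in% names(a)) a[[r]] else 0L) +
              c * (if (r %in% names(b)) b[[r]] else 0L)) %% p
      if (v != 0L) out[[r]] <- v
    }
    out[order(as.integer(names(out)))]
  }
  modInv <- function(a, p) {
    for (x in seq_len(p - 1L)) if ((a * x) %% p == 1L) return(x)
    stop("no inverse")
  }

  lowOwner <- integer(ns)  # low row -> column index
  for (s in seq_len(ns)) {
    repeat {
      l <- low(cols[[s]])
      if (l == 0L || lowOwner[l] == 0L) break
      t <- lowOwner[l]
      c <- ((p - cols[[s]][[as.character(l)]]) *
              modInv(cols[[t]][[as.character(l)]], p)) %% p
      cols[[s]] <- addCol(cols[[s]], cols[[t]], c)
    }
    l <- low(cols[[s]])
    if (l > 0L) lowOwner[l] <- s
  }

  birth <- death <- numeric(0)
  censored <- logical(0)
  for (s in seq_len(ns)) {
    if (simp[[s]]$dim != 1L) next
    l <- low(cols[[s]])
    if (l > 0L) next            # negative edge (pairs with a vertex)
    t <- lowOwner[s]            # triangle killing this edge, if any
    if (t > 0L) {
      if (simp[[s]]$val < simp[[t]]$val) {
        birth <- c(birth, simp[[s]]$val)
        death <- c(death, simp[[t]]$val)
        censored <- c(censored, FALSE)
      }
    } else if (simp[[s]]$val < maxScale) {
      birth <- c(birth, simp[[s]]$val)
      death <- c(death, maxScale)
      censored <- c(censored, TRUE)
    }
  }
  o <- order(birth, death)
  list(birth = birth[o], death = death[o], censored = censored[o])
}

# convenience: compare package diagram against the oracle
expectMatchesOracle <- function(dm, maxScale, p = 2L, tol = 1e-12) {
  dg <- ripsH1(dm, maxScale = maxScale, fieldChar = p)
  or <- bruteForceH1(dm, maxScale, p = p)
  iv <- intervals(dg)
  expect_equal(nrow(iv), length(or$birth))
  if (length(or$birth) > 0L) {
    expect_equal(unname(iv[, 1L]), or$birth, tolerance = tol)
    expect_equal(unname(iv[, 2L]), or$death, tolerance = tol)
    expect_equal(isCensored(dg), or$censored)
  }
}
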