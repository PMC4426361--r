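# Exact minimum signed reversal distance (Hannenhalli-Pevzner) for a linear
# chromosome, scenario reconstruction, and a breadth-first-search oracle for
# small n.
#
# The permutation is framed with 0 and n+1, each element v is doubled into
# the points (2v-1, 2v) (order swapped for negative v), black edges join
# consecutive points between elements, gray edges join values 2i and 2i+1.
# d = (n + 1) - cycles + hurdles + fortress.

.check_signed_perm <- function(order) {
  order <- as.integer(order)
  n <- length(order)
  if (n == 0L) stop("empty permutation")
  if (any(order == 0L) || !setequal(abs(order), seq_len(n)))
    stop("not a signed permutation of 1..n")
  order
}

# breakpoint-graph analysis; returns cycles, hurdles, fortress, n
.breakpoint_graph <- function(order) {
  n <- length(order)
  # point sequence Q (values 0..2n+1), 1-indexed positions 1..2n+2
  Q <- integer(2L * n + 2L)
  Q[1L] <- 0L
  for (j in seq_len(n)) {
    v <- order[j]
    if (v > 0L) {
      Q[2L * j] <- 2L * v - 1L; Q[2L * j + 1L] <- 2L * v
    } else {
      Q[2L * j] <- -2L * v; Q[2L * j + 1L] <- -2L * v - 1L
    }
  }
  Q[2L * n + 2L] <- 2L * n + 1L
  pos <- integer(2L * n + 2L); pos[Q + 1L] <- seq_along(Q)

  # partners by value (0-based values stored at index value+1)
  black <- integer(2L * n + 2L)
  for (k in seq_len(n + 1L)) {
    a <- Q[2L * k - 1L]; b <- Q[2L * k]
    black[a + 1L] <- b; black[b + 1L] <- a
  }
  gray <- integer(2L * n + 2L)
  for (i in 0:n) {
    gray[2L * i + 1L] <- 2L * i + 1L  # value 2i <-> 2i+1
    gray[2L * i + 2L] <- 2L * i
  }

  # cycles: alternate black/gray edges
  cyc_id <- integer(2L * n + 2L)  # by value+1
  n_cyc <- 0L
  for (v0 in 0:(2L * n + 1L)) {
    if (cyc_id[v0 + 1L] != 0L) next
    n_cyc <- n_cyc + 1L
    v <- v0
    repeat {
      cyc_id[v + 1L] <- n_cyc
      v <- black[v + 1L]
      cyc_id[v + 1L] <- n_cyc
      v <- gray[v + 1L]
      if (v == v0) break
    }
  }

  # gray edge list: endpoints (values 2i, 2i+1), their positions, cycle id,
  # orientation (same position parity = oriented)
  ge_lo <- pmin(pos[2L * (0:n) + 1L], pos[2L * (0:n) + 2L])
  ge_hi <- pmax(pos[2L * (0:n) + 1L], pos[2L * (0:n) + 2L])
  ge_cyc <- cyc_id[2L * (0:n) + 1L]
  ge_oriented <- (ge_lo %% 2L) == (ge_hi %% 2L)

  cyc_size <- tabulate(cyc_id, nbins = n_cyc)   # vertices per cycle
  nontrivial <- which(cyc_size > 2L)
  cyc_oriented <- vapply(seq_len(n_cyc), function(cy)
    any(ge_oriented[ge_cyc == cy]), logical(1L))

  list(n = n, n_cycles = n_cyc, cyc_id = cyc_id, pos = pos,
       ge_lo = ge_lo, ge_hi = ge_hi, ge_cyc = ge_cyc,
       nontrivial = nontrivial, cyc_oriented = cyc_oriented)
}

# connected components of the cycle-interleaving graph; returns per-cycle
# component id (NA for trivial cycles) and per-component orientation
.components <- function(bg) {
  nt <- bg$nontrivial
  k <- length(nt)
  if (k == 0L)
    return(list(comp_of_cycle = rep(NA_integer_, bg$n_cycles),
                comp_unoriented = logical(0)))
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  idx_of <- match(seq_len(bg$n_cycles), nt)   # cycle id -> 1..k or NA
  if (k > 1L) {
    for (a in 1:(k - 1L)) for (b in (a + 1L):k) {
      ea <- which(bg$ge_cyc == nt[a]); eb <- which(bg$ge_cyc == nt[b])
      crossed <- FALSE
      for (i in ea) {
        if (any(bg$ge_lo[i] < bg$ge_lo[eb] & bg$ge_lo[eb] < bg$ge_hi[i] &
                bg$ge_hi[i] < bg$ge_hi[eb]) ||
            any(bg$ge_lo[eb] < bg$ge_lo[i] & bg$ge_lo[i] < bg$ge_hi[eb] &
                bg$ge_hi[eb] < bg$ge_hi[i])) { crossed <- TRUE; break }
      }
      if (crossed) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <- ra }
    }
  }
  roots <- vapply(seq_len(k), find, integer(1L))
  comp_lab <- match(roots, unique(roots))
  comp_of_cycle <- rep(NA_integer_, bg$n_cycles)
  comp_of_cycle[nt] <- comp_lab
  n_comp <- max(comp_lab)
  comp_unoriented <- vapply(seq_len(n_comp), function(cmp)
    !any(bg$cyc_oriented[nt[comp_lab == cmp]]), logical(1L))
  list(comp_of_cycle = comp_of_cycle, comp_unoriented = comp_unoriented)
}

# hurdle/fortress count from unoriented components via the circular
# collapsed occurrence sequence of component labels over positions
.hurdles_fortress <- function(bg, comps) {
  un <- which(comps$comp_unoriented)
  if (length(un) == 0L) return(c(h = 0L, f = 0L))
  # component label at each position (NA where not in an unoriented comp)
  lab <- comps$comp_of_cycle[bg$cyc_id]       # by position? cyc_id is by value
  # map positions -> values -> cycle -> component
  val_at_pos <- integer(length(bg$pos)); val_at_pos[bg$pos] <- seq_along(bg$pos) - 1L
  lab <- comps$comp_of_cycle[bg$cyc_id[val_at_pos + 1L]]
  lab[!(lab %in% un)] <- NA_integer_
  seq_lab <- lab[!is.na(lab)]
  collapse_circ <- function(s) {
    if (length(s) == 0L) return(s)
    s <- s[c(TRUE, s[-1L] != s[-length(s)])]
    if (length(s) > 1L && s[1L] == s[length(s)]) s <- s[-length(s)]
    s
  }
  occ <- collapse_circ(seq_lab)
  counts <- table(occ)
  hurdles <- as.integer(names(counts)[counts == 1L])
  h <- length(hurdles)
  if (h == 0L) return(c(h = 0L, f = 0L))
  super <- vapply(hurdles, function(hh) {
    rest <- collapse_circ(seq_lab[seq_lab != hh])
    if (length(rest) == 0L) return(FALSE)
    counts2 <- table(rest)
    newly <- setdiff(as.integer(names(counts2)[counts2 == 1L]), hurdles)
    length(newly) > 0L
  }, logical(1L))
  f <- as.integer(h %% 2L == 1L && all(super) && h >= 3L)
  c(h = h, f = f)
}

#' Minimum signed reversal distance (Hannenhalli-Pevzner)
#'
#' Exact minimum number of reversals transforming a signed permutation into
#' the identity, for a single linear chromosome with fixed orientation:
#' d = (n + 1) - cycles + hurdles + fortress on the framed breakpoint graph.
#'
#' @param order Signed permutation of 1..n (see [shared_signed_order()]).
#' @param orientation `"fixed"` takes the element orientation as given;
#'   `"both"` also scores the globally flipped element and returns the
#'   smaller distance.
#' @return Minimum number of reversals (integer).
#' @export
reversal_distance <- function(order, orientation = c("fixed", "both")) {
  orientation <- match.arg(orientation)
  order <- .check_signed_perm(order)
  d <- .hp_distance(order)
  if (orientation == "both") {
    d2 <- .hp_distance(-rev(order))
    d <- min(d, d2)
  }
  d
}

.hp_distance <- function(order) {
  bg <- .breakpoint_graph(order)
  comps <- .components(bg)
  hf <- .hurdles_fortress(bg, comps)
  (bg$n + 1L) - bg$n_cycles + hf[["h"]] + hf[["f"]]
}

# apply reversal of positions i..j (1-based, inclusive)
.apply_reversal <- function(order, i, j) {
  order[i:j] <- -order[j:i]
  order
}

#' Parsimonious reversal scenario
#'
#' A sequence of exactly `reversal_distance(order)` reversals sorting the
#' permutation to the identity, obtained by repeatedly applying any reversal
#' that decreases the distance by one (one always exists).
#'
#' @param order Signed permutation of 1..n.
#' @return A data.frame with columns `i`, `j` (1-based inclusive reversal
#'   endpoints), in application order; zero rows for the identity.
#' @export
reversal_scenario <- function(order) {
  order <- .check_signed_perm(order)
  n <- length(order)
  steps <- list()
  d <- .hp_distance(order)
  while (d > 0L) {
    found <- FALSE
    for (i in seq_len(n)) {
      for (j in i:n) {
        cand <- .apply_reversal(order, i, j)
        if (.hp_distance(cand) == d - 1L) {
          steps[[length(steps) + 1L]] <- c(i = i, j = j)
          order <- cand
          d <- d - 1L
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found) stop("internal error: no distance-decreasing reversal found")
  }
  if (length(steps) == 0L)
    return(data.frame(i = integer(), j = integer()))
  as.data.frame(do.call(rbind, steps))
}

#' Breadth-first-search reversal distances (independent oracle)
#'
#' Enumerates the whole signed-permutation space of a small n by BFS from
#' the identity and returns a lookup function.  Used as the independent
#' oracle for [reversal_distance()]; feasible up to n = 7 (about 645k
#' states).
#'
#' @param n Permutation length (1..7).
#' @return A function mapping a signed permutation of 1..n to its exact BFS
#'   reversal distance.
#' @export
reversal_distance_bfs <- function(n) {
  if (n < 1L || n > 7L) stop("BFS oracle supports n in 1..7")
  base <- 2L * n
  pw <- base^(0:(n - 1L))
  enc <- function(M) as.integer(colSums((2L * (abs(M) - 1L) + (M < 0)) * pw)) + 1L
  size <- base^n
  dist <- raw(size)
  frontier <- matrix(seq_len(n), ncol = 1L)
  dist[enc(frontier)] <- as.raw(1L)
  pairs <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  level <- 0L
  while (ncol(frontier) > 0L) {
    level <- level + 1L
    nxt <- list()
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      M <- frontier
      M[i:j, ] <- -frontier[j:i, , drop = FALSE]
      cd <- enc(M)
      new <- dist[cd] == as.raw(0L)
      if (any(new)) {
        cd2 <- cd[new]
        first <- !duplicated(cd2)
        dist[cd2[first]] <- as.raw(level + 1L)
        nxt[[length(nxt) + 1L]] <- M[, new, drop = FALSE][, first, drop = FALSE]
      }
    }
    frontier <- if (length(nxt)) do.call(cbind, nxt) else matrix(integer(), n, 0L)
  }
  function(order) {
    order <- .check_signed_perm(order)
    if (length(order) != n) stop("permutation length must be ", n)
    d <- dist[enc(matrix(order, ncol = 1L))]
    as.integer(d) - 1L
  }
}
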