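# Shared fixtures and independent oracles, all built in code.

# Exhaustive path-search oracle for maxima finding, independent of the
# package's flood-fill implementation. For every local-max plateau of value
# v it runs a literal BFS over all pixels of value > v - tol (all paths
# above the tolerance floor) and rejects the plateau if any strictly higher
# pixel is reachable. Equal-valued surviving plateaus connected above the
# floor collapse to the one with the smallest rounded centroid; a plateau
# touching the border at the global maximum value is suppressed.
oracle_find_maxima <- function(px, tol) {
  nr <- nrow(px); nc <- ncol(px)
  dr8 <- c(-1, -1, -1, 0, 0, 1, 1, 1)
  dc8 <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  neigh <- function(r, c) {
    rr <- r + dr8; cc <- c + dc8
    keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    cbind(rr[keep], cc[keep])
  }
  plat_id <- matrix(0L, nr, nc)
  plats <- list()
  for (s in which(plat_id == 0L)) {
    if (plat_id[s] != 0L) next
    r0 <- (s - 1L) %% nr + 1L; c0 <- (s - 1L) %/% nr + 1L
    v <- px[r0, c0]
    queue <- matrix(c(r0, c0), 1)
    plat_id[r0, c0] <- length(plats) + 1L
    members <- queue
    is_cand <- TRUE
    while (nrow(queue) > 0) {
      p <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      nb <- neigh(p[1], p[2])
      for (k in seq_len(nrow(nb))) {
        vr <- nb[k, 1]; vc <- nb[k, 2]
        if (px[vr, vc] > v) is_cand <- FALSE
        if (px[vr, vc] == v && plat_id[vr, vc] == 0L) {
          plat_id[vr, vc] <- length(plats) + 1L
          queue <- rbind(queue, c(vr, vc))
          members <- rbind(members, c(vr, vc))
        }
      }
    }
    touches <- any(members[, 1] %in% c(1L, nr)) || any(members[, 2] %in% c(1L, nc))
    cen <- colMeans(members)  # 1-based
    plats[[length(plats) + 1L]] <- list(
      v = v, members = members, cand = is_cand, border = touches,
      cen = c(ceiling(cen[1] - 1 - 0.5), ceiling(cen[2] - 1 - 0.5)))
  }
  gmax <- max(px)
  acc <- logical(length(plats))
  reach <- vector("list", length(plats))
  for (i in seq_along(plats)) {
    pl <- plats[[i]]
    if (!pl$cand) next
    if (pl$border && pl$v == gmax) next
    flo <- pl$v - tol
    seen <- matrix(FALSE, nr, nc)
    seen[pl$members] <- TRUE
    queue <- pl$members
    ok <- TRUE
    touched <- integer(0)
    while (nrow(queue) > 0 && ok) {
      p <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      nb <- neigh(p[1], p[2])
      for (k in seq_len(nrow(nb))) {
        vr <- nb[k, 1]; vc <- nb[k, 2]
        if (seen[vr, vc]) next
        val <- px[vr, vc]
        if (val > pl$v) { ok <- FALSE; break }
        if (val > flo) {
          seen[vr, vc] <- TRUE
          queue <- rbind(queue, c(vr, vc))
          if (val == pl$v) touched <- c(touched, plat_id[vr, vc])
        }
      }
    }
    acc[i] <- ok
    reach[[i]] <- unique(touched)
  }
  # group equal-valued accepted plateaus that reach one another
  group <- seq_along(plats)
  find_g <- function(x) { while (group[x] != x) x <- group[x]; x }
  for (i in seq_along(plats)) {
    if (!acc[i]) next
    for (j in reach[[i]]) if (acc[j]) group[find_g(j)] <- find_g(i)
  }
  pts <- NULL
  for (g in unique(vapply(which(acc), find_g, integer(1)))) {
    ids <- which(acc & vapply(seq_along(plats), find_g, integer(1)) == g)
    cens <- do.call(rbind, lapply(plats[ids], `[[`, "cen"))
    best <- order(cens[, 1], cens[, 2])[1]
    pts <- rbind(pts, cens[best, ])
  }
  if (is.null(pts)) return(data.frame(row = integer(0), col = integer(0)))
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  data.frame(row = pts[, 1], col = pts[, 2])
}

# brute-force particle filter used to audit extract_intervein_regions:
# labels 4-connected components with a plain two-pass scan, fills holes by
# checking background reachability from the border, then applies the
# min-area and border rules as pure set operations
oracle_region_masks <- function(class_map, min_area = 200) {
  fg <- class_map == 2L
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (s in which(fg & lab == 0L)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    stack <- s
    lab[s] <- nxt
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
      for (q in c(if (r > 1) p - 1L, if (r < nr) p + 1L,
                  if (c > 1) p - nr, if (c < nc) p + nr)) {
        if (fg[q] && lab[q] == 0L) { lab[q] <- nxt; stack <- c(stack, q) }
      }
    }
  }
  out <- list()
  for (i in seq_len(nxt)) {
    comp <- lab == i
    # fill holes: complement components not touching the border
    bg <- !comp
    bglab <- matrix(0L, nr, nc)
    bnxt <- 0L
    for (s in which(bg & bglab == 0L)) {
      if (bglab[s] != 0L) next
      bnxt <- bnxt + 1L
      stack <- s; bglab[s] <- bnxt
      while (length(stack)) {
        p <- stack[length(stack)]; stack <- stack[-length(stack)]
        r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
        for (q in c(if (r > 1) p - 1L, if (r < nr) p + 1L,
                    if (c > 1) p - nr, if (c < nc) p + nr)) {
          if (bg[q] && bglab[q] == 0L) { bglab[q] <- bnxt; stack <- c(stack, q) }
        }
      }
    }
    border_ids <- unique(c(bglab[1, ], bglab[nr, ], bglab[, 1], bglab[, nc]))
    filled <- comp | (bg & !(bglab %in% setdiff(border_ids, 0L)))
    touches <- any(filled[1, ]) || any(filled[nr, ]) ||
      any(filled[, 1]) || any(filled[, nc])
    if (sum(filled) >= min_area && !touches)
      out[[length(out) + 1L]] <- filled
  }
  out
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# memoized fixtures (synthetic wings are deterministic, so caching across
# test files changes nothing but wall time)
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_wing_params <- function(...) {
  wing_params(width = 640, height = 480, ...)
}

# half-scale wing: large enough that 75 px squares fit between veins
mid_wing_params <- function(...) {
  wing_params(width = 1040, height = 772, ...)
}

clean_params <- function(...) {
  wing_params(coincident_fraction = 0, small_faint_fraction = 0,
              noise_sd = 0, dirt_specks = 0, ...)
}
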