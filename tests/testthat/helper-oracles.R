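# Independent oracles: brute-force flood fill for spot detection, direct
# rank-formula and exhaustive-permutation references for the rank tests.
# These deliberately share no code with the package implementation.

# Flood-fill connected components over a logical mask, by depth-first
# search with an explicit pixel stack.  Returns a list of sorted linear
# pixel index vectors, ordered by smallest member.
flood_fill_components <- function(mask, connectivity = 8) {
  h <- nrow(mask)
  w <- ncol(mask)
  if (connectivity == 8) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1)
    dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 1, 0, 0)
    dc <- c(0, 0, -1, 1)
  }
  lab <- matrix(0L, h, w)
  stack <- integer(sum(mask))
  comp <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    lab[start] <- comp
    top <- 1L
    stack[1] <- start
    while (top > 0L) {
      cur <- stack[top]
      top <- top - 1L
      r <- ((cur - 1L) %% h) + 1L
      cc0 <- ((cur - 1L) %/% h) + 1L
      for (k in seq_along(dr)) {
        rr <- r + dr[k]
        cc <- cc0 + dc[k]
        if (rr >= 1L && rr <= h && cc >= 1L && cc <= w &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- comp
          top <- top + 1L
          stack[top] <- (cc - 1L) * h + rr
        }
      }
    }
  }
  idx <- which(lab != 0L)
  comps <- unname(split(idx, lab[idx]))
  comps[order(vapply(comps, min, numeric(1)))]
}

# Spot summaries (centroid, area, peak, integrated) computed from a pixel
# set by plain loops — the reference for detect_spots.
oracle_spot_summary <- function(img, pixels, background, pixel_size_um) {
  h <- nrow(img)
  rows <- ((pixels - 1) %% h) + 1
  cols <- ((pixels - 1) %/% h) + 1
  wts <- img[pixels] - background
  list(
    n_pixels = length(pixels),
    area_um2 = length(pixels) * pixel_size_um^2,
    centroid_x_um = sum(wts * (cols - 0.5)) / sum(wts) * pixel_size_um,
    centroid_y_um = sum(wts * (rows - 0.5)) / sum(wts) * pixel_size_um,
    peak = max(wts),
    integrated = sum(wts)
  )
}

# Direct evaluation of the tie-corrected Kruskal-Wallis statistic:
# H = [12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2] / [1 - sum(t^3-t)/(N^3-N)]
kw_H_direct <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, idx, mean)
  n_i <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(n_i * (rbar - (N + 1) / 2)^2)
  t <- table(x)
  C <- 1 - sum(t^3 - t) / (N^3 - N)
  H / C
}

# All distinct assignments of N items into groups of the given sizes,
# enumerated recursively via combinations.
all_assignments <- function(sizes) {
  N <- sum(sizes)
  recurse <- function(remaining, sizes_left) {
    if (length(sizes_left) == 1L) return(list(list(remaining)))
    picks <- utils::combn(remaining, sizes_left[1], simplify = FALSE)
    out <- list()
    for (p in picks) {
      for (rest in recurse(setdiff(remaining, p), sizes_left[-1])) {
        out[[length(out) + 1]] <- c(list(p), rest)
      }
    }
    out
  }
  recurse(seq_len(N), sizes)
}

# Exhaustive permutation p value for the Kruskal-Wallis statistic.
kw_perm_p <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  H_obs <- kw_H_direct(groups)
  assigns <- all_assignments(sizes)
  Hs <- vapply(assigns, function(a) {
    kw_H_direct(lapply(a, function(ix) x[ix]))
  }, numeric(1))
  mean(Hs >= H_obs - 1e-9)
}
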