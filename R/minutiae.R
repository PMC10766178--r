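# Galton-Henry feature-point extraction from the ridge skeleton:
# crossing-number typing, compound-structure relabelling (eyes, spurs,
# short ridges, crossovers), level-3 sweat-pore detection, and artifact
# filtering.

MINUTIA_TYPES <- c("core", "termination", "bifurcation", "trifurcation",
                   "crossover", "eye", "lake", "spur", "short_ridge",
                   "island", "hook", "pore")

#' Construct a minutia set
#'
#' @param df data.frame with columns `x`, `y` (pixel coordinates, 1-based),
#'   `type` (one of the Galton-Henry vocabulary:
#'   `r paste(MINUTIA_TYPES, collapse = ", ")`) and optionally `quality`
#'   in \[0, 1\].
#' @param core optional `core_point` anchor.
#' @param source_image_id identifier carried into reports.
#' @return A `minutia_set`: the data.frame in canonical order (by `y`,
#'   then `x`, then `type`) with attributes `core` and `source_image_id`.
#' @export
minutia_set <- function(df = NULL, core = NULL, source_image_id = NA_character_) {
  if (is.null(df))
    df <- data.frame(x = numeric(), y = numeric(), type = character(),
                     quality = numeric())
  stopifnot(is.data.frame(df), all(c("x", "y", "type") %in% names(df)))
  if (!"quality" %in% names(df)) df$quality <- rep(1, nrow(df))
  bad <- setdiff(unique(df$type), MINUTIA_TYPES)
  if (length(bad))
    stop_lfp("precondition", "unknown minutia type(s): %s",
             paste(bad, collapse = ", "))
  df <- df[order(df$y, df$x, df$type), c("x", "y", "type", "quality"),
           drop = FALSE]
  df <- df[!duplicated(df[c("x", "y", "type")]), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, core = core, source_image_id = source_image_id,
            class = c("minutia_set", "data.frame"))
}

#' @export
print.minutia_set <- function(x, ...) {
  cat(sprintf("<minutia_set: %d points (%s)%s>\n", nrow(x),
              paste(names(table(x$type)), table(x$type),
                    sep = ":", collapse = " "),
              if (!is.null(attr(x, "core"))) " +core" else ""))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}

set_core <- function(ms, core) { attr(ms, "core") <- core; ms }

#' Extract crossing-number minutiae from a skeleton
#'
#' Computes the crossing number at every skeleton pixel and reports
#' CN = 1 as `termination`, CN = 3 as `bifurcation` and CN >= 4 as
#' `trifurcation` (a trifurcation/crossover candidate that
#' [classify_compound()] may refine). The result is deterministic for a
#' given skeleton and ordered canonically.
#'
#' @param skel a skeleton `binary_image` (from [skeletonize()]).
#' @param quality optional matrix of per-pixel quality in \[0, 1\] (e.g.
#'   upsampled orientation coherence); defaults to 1.
#' @return A [minutia_set()].
#' @export
extract_minutiae <- function(skel, quality = NULL) {
  stopifnot(inherits(skel, "binary_image"))
  m <- skel$pixels
  if (sum(m) == 0L)
    stop_lfp("no_features", "empty skeleton: no feature points")
  cn <- cn_map(m)
  cn[m == 0L] <- -1L
  pick <- function(cond, type) {
    w <- which(cond)
    if (!length(w)) return(NULL)
    data.frame(x = ((w - 1) %/% nrow(m)) + 1,
               y = ((w - 1) %% nrow(m)) + 1,
               type = type)
  }
  df <- rbind(pick(cn == 1L, "termination"),
              pick(cn == 3L, "bifurcation"),
              pick(cn >= 4L, "trifurcation"))
  if (is.null(df) || !nrow(df))
    stop_lfp("no_features", "skeleton has no CN != 2 pixels")
  df$quality <- if (is.null(quality)) 1 else quality[cbind(df$y, df$x)]
  minutia_set(df)
}

# ---- skeleton graph -------------------------------------------------------
# Nodes are minutia pixels (CN != 2); edges are ridge segments traced
# through CN = 2 pixels. Used by classify_compound and the synthetic
# generator's ground-truth census.

skeleton_graph <- function(m) {
  cn <- cn_map(m); cn[m == 0L] <- -1L
  node_idx <- which(cn != 2L & cn >= 0L)
  is_node <- matrix(FALSE, nrow(m), ncol(m)); is_node[node_idx] <- TRUE
  h <- nrow(m)
  xy <- function(w) c(y = ((w - 1) %% h) + 1, x = ((w - 1) %/% h) + 1)
  nbrs <- function(r, c) {
    rr <- r + zs_offsets[, 1]; cc <- c + zs_offsets[, 2]
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= ncol(m)
    ok[ok] <- m[cbind(rr[ok], cc[ok])] == 1L
    cbind(rr[ok], cc[ok])
  }
  edges <- list()
  seen <- new.env(hash = TRUE)
  edge_key <- function(p, q) paste(min(p, q), max(p, q), sep = "-")
  lin <- function(r, c) (c - 1) * h + r
  max_steps <- sum(m) + 8L
  on_path <- matrix(FALSE, h, ncol(m))   # cleared after every trace
  for (w in node_idx) {
    p0 <- xy(w)
    first_steps <- nbrs(p0["y"], p0["x"])
    for (k in seq_len(nrow(first_steps))) {
      nb <- first_steps[k, , drop = FALSE]
      buf <- integer(256); n <- 0L
      push <- function(r, c) {
        if (n == length(buf)) buf <<- c(buf, integer(length(buf)))
        n <<- n + 1L
        buf[n] <<- lin(r, c)
        on_path[r, c] <<- TRUE
      }
      push(p0["y"], p0["x"])
      prev <- c(p0["y"], p0["x"]); cur <- c(nb[1], nb[2])
      steps <- 0
      while (steps < max_steps) {
        closed <- on_path[cur[1], cur[2]]   # trace re-entered itself
        push(cur[1], cur[2])
        if (is_node[cur[1], cur[2]] || closed) break
        cand <- nbrs(cur[1], cur[2])
        cand <- cand[!(cand[, 1] == prev[1] & cand[, 2] == prev[2]), ,
                     drop = FALSE]
        # avoid stepping back onto the current trace (tight turns)
        if (nrow(cand) > 1) {
          onp <- on_path[cand]
          if (any(!onp)) cand <- cand[!onp, , drop = FALSE]
        }
        if (!nrow(cand)) break
        prev <- cur; cur <- c(cand[1, 1], cand[1, 2])
        steps <- steps + 1
      }
      ids <- buf[seq_len(n)]
      on_path[ids] <- FALSE
      path <- cbind(((ids - 1L) %% h) + 1L, ((ids - 1L) %/% h) + 1L)
      endw <- lin(cur[1], cur[2])
      # identify an edge by its endpoints plus a fingerprint of its
      # interior pixels, so the two equal-length arms of an enclosure
      # stay distinct edges
      interior <- if (nrow(path) > 2) {
        ip <- lin(path[2:(nrow(path) - 1), 1], path[2:(nrow(path) - 1), 2])
        paste(min(ip), max(ip), sum(ip), sep = "/")
      } else "none"
      key <- paste(edge_key(w, endw), nrow(path), interior)
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        edges[[length(edges) + 1]] <- list(from = w, to = endw,
                                           length = nrow(path) - 1,
                                           path = path)
      }
    }
  }
  list(nodes = node_idx, cn = cn, edges = edges, h = h)
}

#' Re-label compound Galton-Henry structures
#'
#' Walks the skeleton graph and refines raw crossing-number types:
#' \itemize{
#'   \item two bifurcations joined by both arms of a cycle shorter than
#'     `L_eye` become one `eye` (an enclosure: a ridge that bifurcates and
#'     re-joins over a short distance);
#'   \item a branch shorter than `L_spur` leaving a through-ridge and
#'     ending in a termination becomes a `spur` (the branch termination is
#'     consumed);
#'   \item a free segment with two terminations shorter than `L_short`
#'     becomes a `short_ridge`;
#'   \item two bifurcations joined by a path shorter than `L_cross` whose
#'     four outer arms are long become one `crossover`; a CN >= 4 pixel is
#'     a `crossover` when exactly 4 long arms leave it, else stays
#'     `trifurcation`.
#' }
#' Candidates matched by no rule keep their raw type.
#'
#' @param ms minutia set from [extract_minutiae()] (same skeleton).
#' @param skel the skeleton the set came from.
#' @param L_eye,L_spur,L_short,L_cross length scales in pixels; defaults
#'   30, 8, 15, 6 assume a ridge period near 9 px.
#' @return A re-labelled `minutia_set`.
#' @export
classify_compound <- function(ms, skel, L_eye = 30, L_spur = 8,
                              L_short = 15, L_cross = 6) {
  stopifnot(inherits(ms, "minutia_set"), inherits(skel, "binary_image"))
  m <- skel$pixels
  g <- skeleton_graph(m)
  h <- g$h
  lin <- function(x, y) (x - 1) * h + y
  keyed <- new.env(hash = TRUE)
  for (i in seq_len(nrow(ms)))
    keyed[[as.character(lin(ms$x[i], ms$y[i]))]] <- i
  row_of <- function(w) keyed[[as.character(w)]]
  consumed <- rep(FALSE, nrow(ms))
  extra <- list()
  type <- ms$type

  deg <- table(c(vapply(g$edges, `[[`, 0, "from"),
                 vapply(g$edges, `[[`, 0, "to")))
  node_deg <- function(w) { d <- deg[as.character(w)]; if (is.na(d)) 0 else d }

  # eyes: two bifurcation nodes joined by >= 2 distinct paths, cycle short
  bif_nodes <- g$nodes[g$cn[g$nodes] == 3L]
  if (length(bif_nodes) >= 2) {
    ek <- vapply(g$edges, function(e)
      paste(min(e$from, e$to), max(e$from, e$to)), "")
    for (key in unique(ek[duplicated(ek)])) {
      es <- g$edges[ek == key]
      if (length(es) < 2) next
      a <- es[[1]]$from; b <- es[[1]]$to
      if (a == b) next
      if (!(a %in% bif_nodes && b %in% bif_nodes)) next
      lens <- sort(vapply(es, `[[`, 0, "length"))
      if (sum(lens[1:2]) >= L_eye) next
      ia <- row_of(a); ib <- row_of(b)
      if (is.null(ia) || is.null(ib) || consumed[ia] || consumed[ib]) next
      consumed[c(ia, ib)] <- TRUE
      cyc <- rbind(es[[1]]$path, es[[2]]$path)
      extra[[length(extra) + 1]] <- data.frame(
        x = round(mean(cyc[, 2])), y = round(mean(cyc[, 1])),
        type = "eye", quality = mean(ms$quality[c(ia, ib)]))
    }
  }

  # spurs: short branch from a bifurcation to a termination
  for (e in g$edges) {
    cf <- g$cn[e$from]; ct <- g$cn[e$to]
    if (e$length >= L_spur) next
    pair <- NULL
    if (cf == 3L && ct == 1L) pair <- c(e$from, e$to)
    if (cf == 1L && ct == 3L) pair <- c(e$to, e$from)
    if (is.null(pair)) next
    ib <- row_of(pair[1]); it <- row_of(pair[2])
    if (is.null(ib) || is.null(it) || consumed[ib] || consumed[it]) next
    consumed[c(ib, it)] <- TRUE
    extra[[length(extra) + 1]] <- data.frame(
      x = ms$x[ib], y = ms$y[ib], type = "spur",
      quality = ms$quality[ib])
  }

  # short ridges / islands: an isolated segment between two terminations
  for (e in g$edges) {
    if (g$cn[e$from] != 1L || g$cn[e$to] != 1L) next
    if (e$from == e$to) next
    if (node_deg(e$from) != 1 || node_deg(e$to) != 1) next
    if (e$length >= L_short) next
    i1 <- row_of(e$from); i2 <- row_of(e$to)
    if (is.null(i1) || is.null(i2) || consumed[i1] || consumed[i2]) next
    consumed[c(i1, i2)] <- TRUE
    mid <- e$path[ceiling(nrow(e$path) / 2), ]
    extra[[length(extra) + 1]] <- data.frame(
      x = mid[2], y = mid[1], type = "short_ridge",
      quality = mean(ms$quality[c(i1, i2)]))
  }

  # crossovers: two bifurcations fused across a very short bridge
  for (e in g$edges) {
    if (g$cn[e$from] != 3L || g$cn[e$to] != 3L) next
    if (e$from == e$to || e$length >= L_cross) next
    ia <- row_of(e$from); ib <- row_of(e$to)
    if (is.null(ia) || is.null(ib) || consumed[ia] || consumed[ib]) next
    arms <- Filter(function(o) (o$from %in% c(e$from, e$to) ||
                                  o$to %in% c(e$from, e$to)) &&
                     o$length > L_cross, g$edges)
    if (length(arms) < 4) next
    consumed[c(ia, ib)] <- TRUE
    mid <- e$path[ceiling(nrow(e$path) / 2), ]
    extra[[length(extra) + 1]] <- data.frame(
      x = mid[2], y = mid[1], type = "crossover",
      quality = mean(ms$quality[c(ia, ib)]))
  }

  out <- as.data.frame(ms)[!consumed, , drop = FALSE]
  out$type <- type[!consumed]
  if (length(extra)) out <- rbind(out, do.call(rbind, extra))
  minutia_set(out, core = attr(ms, "core"),
              source_image_id = attr(ms, "source_image_id"))
}

#' Detect level-3 sweat pores
#'
#' A pore is a background-colored blob fully enclosed by ridge pixels
#' (a hole in the ridge mask) with area inside `[A_min, A_max]`.
#' Detection labels the 4-connected background components; any component
#' that does not touch the image border is enclosed.
#'
#' @param bin ridge-polarity `binary_image` (the un-thinned ridge mask).
#' @param A_min,A_max pore area window in px^2 (defaults 1 and 20).
#' @return A `minutia_set` of `pore` points at blob centroids.
#' @export
detect_pores <- function(bin, A_min = 1, A_max = 20) {
  stopifnot(inherits(bin, "binary_image"))
  if (!bin$ridge_is_one)
    stop_lfp("precondition", "detect_pores requires ridge polarity")
  m <- bin$pixels
  bg <- 1L - m
  lab <- from_ebimage(EBImage::bwlabel(as_ebimage(bg)))
  if (max(lab) == 0) return(minutia_set())
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ],
                            lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- setdiff(which(sizes >= A_min & sizes <= A_max), border_labels)
  if (!length(keep)) return(minutia_set())
  rows <- row(lab); cols <- col(lab)
  df <- do.call(rbind, lapply(keep, function(l) {
    sel <- lab == l
    data.frame(x = round(mean(cols[sel])), y = round(mean(rows[sel])),
               type = "pore", quality = 1)
  }))
  minutia_set(df)
}

#' Filter minutiae artifacts
#'
#' Deterministic cleanup: drops points within `border_margin` of the image
#' edge (and, when a segmentation `mask` is given, points outside the mask
#' or within `border_margin` of its boundary), then removes pairs of
#' terminations closer than `min_separation` -- the signature of a broken
#' ridge re-entering as two facing endpoints.
#'
#' @param ms a `minutia_set`.
#' @param dim_img `c(rows, cols)` of the source image.
#' @param border_margin pixels (default 12).
#' @param min_separation pixels (default 5).
#' @param mask optional logical/0-1 matrix marking the fingerprint area.
#' @param mask_margin exclusion distance from the mask boundary (default
#'   6; boundary minutiae are unreliable but a narrower band than the
#'   image-border margin keeps more of a partially occluded print).
#' @return The filtered `minutia_set`.
#' @export
filter_minutiae <- function(ms, dim_img, border_margin = 12,
                            min_separation = 5, mask = NULL,
                            mask_margin = 6) {
  stopifnot(inherits(ms, "minutia_set"))
  if (!nrow(ms)) return(ms)
  h <- dim_img[1]; w <- dim_img[2]
  keep <- ms$x > border_margin & ms$x <= w - border_margin &
    ms$y > border_margin & ms$y <= h - border_margin
  if (!is.null(mask)) {
    mk <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
    # distance-to-boundary via erosion: a point survives if a margin-sized
    # neighborhood around it is fully inside the mask
    br <- max(1L, as.integer(mask_margin))
    er <- from_ebimage(EBImage::erode(as_ebimage(mk),
                                      EBImage::makeBrush(2L * br + 1L,
                                                         "disc")))
    keep <- keep & er[cbind(pmin(pmax(round(ms$y), 1), h),
                            pmin(pmax(round(ms$x), 1), w))] > 0
  }
  out <- as.data.frame(ms)[keep, , drop = FALSE]
  # facing-termination merge
  it <- which(out$type == "termination")
  if (length(it) >= 2) {
    d <- as.matrix(dist(out[it, c("x", "y")]))
    diag(d) <- Inf
    drop <- it[apply(d < min_separation, 1, any)]
    if (length(drop)) out <- out[-drop, , drop = FALSE]
  }
  minutia_set(out, core = attr(ms, "core"),
              source_image_id = attr(ms, "source_image_id"))
}
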