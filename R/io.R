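# Minutiae exchange (JSON and flat CSV), match reports, and annotated
# overlays.

#' Write / read a minutia set as JSON
#'
#' The JSON schema carries one record per point (`x`, `y`, `type`,
#' `quality`), the `source_image_id`, and the core anchor
#' (`core: {a, b, kind}`) when present. The reader validates the type
#' vocabulary and round-trips the set exactly.
#'
#' @param ms a `minutia_set`.
#' @param path file path.
#' @return `write_minutiae_json`: `path` invisibly;
#'   `read_minutiae_json`: a `minutia_set`.
#' @export
write_minutiae_json <- function(ms, path) {
  stopifnot(inherits(ms, "minutia_set"))
  core <- attr(ms, "core")
  obj <- list(schema = "lfpmatch-minutiae/1",
              source_image_id = attr(ms, "source_image_id"),
              core = if (!is.null(core))
                list(a = core$a, b = core$b, kind = core$kind,
                     poincare_index = core$poincare_index),
              points = as.data.frame(ms))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_minutiae_json
#' @export
read_minutiae_json <- function(path) {
  if (!file.exists(path)) stop_lfp("io", "no such file: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- obj$points
  if (is.null(pts) || !nrow(as.data.frame(pts)))
    pts <- data.frame(x = numeric(), y = numeric(), type = character(),
                      quality = numeric())
  core <- NULL
  if (!is.null(obj$core) && !is.null(obj$core$a))
    core <- structure(list(a = obj$core$a, b = obj$core$b,
                           kind = obj$core$kind,
                           poincare_index = obj$core$poincare_index),
                      class = "core_point")
  minutia_set(as.data.frame(pts), core = core,
              source_image_id = if (is.null(obj$source_image_id))
                NA_character_ else obj$source_image_id)
}

#' Write / read a minutia set as flat CSV
#'
#' Columns `x`, `y`, `type`, `quality`; the core, when present, is stored
#' as an extra row of type `core`.
#'
#' @param ms a `minutia_set`; `path` file path.
#' @return `write_minutiae_csv`: `path` invisibly; `read_minutiae_csv`:
#'   a `minutia_set`.
#' @export
write_minutiae_csv <- function(ms, path) {
  df <- as.data.frame(ms)
  core <- attr(ms, "core")
  if (!is.null(core))
    df <- rbind(df, data.frame(x = core$a, y = core$b, type = "core",
                               quality = 1))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_minutiae_csv
#' @export
read_minutiae_csv <- function(path) {
  if (!file.exists(path)) stop_lfp("io", "no such file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  core <- NULL
  ic <- which(df$type == "core")
  if (length(ic)) {
    core <- structure(list(a = df$x[ic[1]], b = df$y[ic[1]], kind = "core",
                           poincare_index = NA_real_),
                      class = "core_point")
    df <- df[-ic, , drop = FALSE]
  }
  minutia_set(df, core = core)
}

#' Write a versioned JSON match report
#'
#' Serializes a `match_result` with its per-point terms, correspondence,
#' stage reports and the configuration used, for full provenance. The
#' percentage is also rendered as a 2-decimal string (e.g. `"86.94"`).
#'
#' @param result a `match_result`.
#' @param stages list of stage reports (from the `artifacts` attribute or
#'   built manually); must be supplied.
#' @param path output path.
#' @param config the `lfp_config` used.
#' @return `path`, invisibly.
#' @export
write_match_report <- function(result, stages, path, config = NULL) {
  stopifnot(inherits(result, "match_result"))
  if (missing(stages) || is.null(stages))
    stop_lfp("schema", "a match report requires the stage list")
  cfg <- resolve_config(config)
  obj <- list(
    schema = "lfpmatch-report/1",
    P = result$P,
    percent = result$percent,
    percent_printed = sprintf("%.2f", result$percent),
    m_used = result$m_used,
    per_point_terms = result$per_point_terms,
    correspondence = list(
      pairs = unname(apply(result$correspondence$pairs, 1, as.list)),
      unpaired_sample = result$correspondence$unpaired_sample,
      unpaired_control = result$correspondence$unpaired_control),
    stages = stages,
    config = unclass(cfg))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a match report back into a `match_result`
#'
#' @param path report path.
#' @return A `match_result` (score fields and correspondence).
#' @export
read_match_report <- function(path) {
  if (!file.exists(path)) stop_lfp("io", "no such file: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "lfpmatch-report/1"))
    stop_lfp("schema", "not an lfpmatch report: %s", path)
  pr <- obj$correspondence$pairs
  pairs <- if (is.data.frame(pr) && nrow(pr)) {
    cbind(sample = as.integer(pr$sample), control = as.integer(pr$control))
  } else if (is.list(pr) && length(pr)) {
    do.call(rbind, lapply(pr, function(p)
      c(sample = as.integer(p$sample), control = as.integer(p$control))))
  } else matrix(0L, 0, 2, dimnames = list(NULL, c("sample", "control")))
  corr <- structure(list(pairs = pairs,
                         unpaired_sample = obj$correspondence$unpaired_sample,
                         unpaired_control = obj$correspondence$unpaired_control),
                    class = "correspondence")
  structure(list(P = obj$P, percent = obj$percent, m_used = obj$m_used,
                 per_point_terms = obj$per_point_terms,
                 correspondence = corr),
            class = "match_result")
}

#' Write an annotated overlay PNG
#'
#' Draws numbered, type-coded markers at minutia positions over the
#' grayscale image: squares for terminations, diamonds for bifurcations
#' and trifurcations, circles for compound types and pores, a cross for
#' the core. Output bytes are deterministic for fixed input.
#'
#' @param img a `gray_image` (raw stage).
#' @param ms a `minutia_set`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
annotate_overlay <- function(img, ms, path) {
  stopifnot(inherits(img, "gray_image"), inherits(ms, "minutia_set"))
  p <- img$pixels / 255
  h <- nrow(p); w <- ncol(p)
  if (nrow(ms) && (any(ms$x < 1 | ms$x > w) || any(ms$y < 1 | ms$y > h)))
    stop_lfp("precondition", "minutia outside image bounds")
  rgb <- array(rep(p, 3), c(h, w, 3))
  put <- function(ys, xs, col) {
    ok <- ys >= 1 & ys <= h & xs >= 1 & xs <= w
    for (k in 1:3) {
      ch <- rgb[, , k]
      ch[cbind(ys[ok], xs[ok])] <- col[k]
      rgb[, , k] <<- ch
    }
  }
  marker <- function(x, y, shape, col) {
    x <- round(x); y <- round(y); r <- 3
    if (shape == "square") {
      xs <- c((x - r):(x + r), (x - r):(x + r),
              rep(x - r, 2 * r + 1), rep(x + r, 2 * r + 1))
      ys <- c(rep(y - r, 2 * r + 1), rep(y + r, 2 * r + 1),
              (y - r):(y + r), (y - r):(y + r))
    } else if (shape == "diamond") {
      off <- 0:r
      xs <- c(x + off, x - off, x + off, x - off)
      ys <- c(y - r + off, y - r + off, y + r - off, y + r - off)
    } else if (shape == "circle") {
      ang <- seq(0, 2 * pi, length.out = 24)
      xs <- round(x + r * cos(ang)); ys <- round(y + r * sin(ang))
    } else { # cross
      xs <- c((x - r):(x + r), rep(x, 2 * r + 1))
      ys <- c(rep(y, 2 * r + 1), (y - r):(y + r))
    }
    put(ys, xs, col)
  }
  shape_of <- function(type) switch(type,
    termination = "square",
    bifurcation = , trifurcation = "diamond",
    core = "cross",
    "circle")
  col_of <- function(type) switch(type,
    termination = c(1, 0, 0),
    bifurcation = c(0, 0.4, 1), trifurcation = c(0, 0.7, 1),
    pore = c(0, 0.8, 0),
    core = c(1, 0.8, 0),
    c(1, 0, 1))
  if (nrow(ms)) {
    for (i in seq_len(nrow(ms)))
      marker(ms$x[i], ms$y[i], shape_of(ms$type[i]), col_of(ms$type[i]))
    # index label: small tick column left of each marker (i ticks)
    for (i in seq_len(nrow(ms))) {
      n <- min(i, 9)
      put(round(ms$y[i]) - 4 + seq_len(n) - 1,
          rep(round(ms$x[i]) - 5, n), c(1, 1, 0))
    }
  }
  core <- attr(ms, "core")
  if (!is.null(core)) marker(core$a, core$b, "cross", col_of("core"))
  png::writePNG(rgb, path)
  invisible(path)
}
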