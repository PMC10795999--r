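# Horn-Schunck optical flow and eccentricity-resolved flow / luminance
# diagnostics for rendered looming stimuli.

## shift a matrix by (di, dj) with edge replication
shift_mat <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + di, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
  m[ri, ci, drop = FALSE]
}

hs_derivatives <- function(a, b) {
  ## classical Horn-Schunck (1981) forward-difference averaging stencils,
  ## estimated at cell centres between the two frames
  f <- function(m) shift_mat(m, 0, 1) - m +
    shift_mat(m, 1, 1) - shift_mat(m, 1, 0)
  g <- function(m) shift_mat(m, 1, 0) - m +
    shift_mat(m, 1, 1) - shift_mat(m, 0, 1)
  Ex <- (f(a) + f(b)) / 4
  Ey <- (g(a) + g(b)) / 4
  Et <- (b - a + shift_mat(b, 1, 0) - shift_mat(a, 1, 0) +
           shift_mat(b, 0, 1) - shift_mat(a, 0, 1) +
           shift_mat(b, 1, 1) - shift_mat(a, 1, 1)) / 4
  list(Ex = Ex, Ey = Ey, Et = Et)
}

hs_local_avg <- function(m) {
  (shift_mat(m, -1, 0) + shift_mat(m, 1, 0) +
     shift_mat(m, 0, -1) + shift_mat(m, 0, 1)) / 6 +
    (shift_mat(m, -1, -1) + shift_mat(m, -1, 1) +
       shift_mat(m, 1, -1) + shift_mat(m, 1, 1)) / 12
}

#' Horn-Schunck optical flow between two frames
#'
#' Dense optical flow under the brightness-constancy assumption with a
#' global smoothness penalty, solved by the classical Jacobi iteration
#' `u = u_avg - Ex (Ex u_avg + Ey v_avg + Et) / (alpha^2 + Ex^2 + Ey^2)`.
#' Derivatives use the original forward-difference averaging stencils;
#' boundaries are handled by edge replication. Deterministic.
#'
#' @param frame_a,frame_b Grayscale matrices of identical shape.
#' @param alpha Smoothness weight (> 0).
#' @param n_iterations Number of Jacobi iterations (>= 1).
#' @return An object of class `flow_field` with horizontal (`u`, +x
#'   rightward in column direction) and vertical (`v`) flow in pixels/frame.
#' @export
horn_schunck_flow <- function(frame_a, frame_b, alpha = 1, n_iterations = 100) {
  if (!identical(dim(frame_a), dim(frame_b))) {
    stop_domain("frames must have the same shape")
  }
  if (alpha <= 0) stop_domain("`alpha` must be > 0")
  if (n_iterations < 1) stop_domain("`n_iterations` must be >= 1")
  d <- hs_derivatives(frame_a, frame_b)
  u <- matrix(0, nrow(frame_a), ncol(frame_a))
  v <- u
  denom <- alpha^2 + d$Ex^2 + d$Ey^2
  for (k in seq_len(n_iterations)) {
    ub <- hs_local_avg(u)
    vb <- hs_local_avg(v)
    t <- (d$Ex * ub + d$Ey * vb + d$Et) / denom
    u <- ub - d$Ex * t
    v <- vb - d$Ey * t
  }
  structure(list(u = u, v = v, alpha = alpha, n_iterations = n_iterations),
            class = "flow_field")
}

## Horn-Schunck energy: data term + alpha^2 * smoothness term; used in tests
## to confirm that more iterations descend the functional.
hs_energy <- function(frame_a, frame_b, flow) {
  d <- hs_derivatives(frame_a, frame_b)
  data <- sum((d$Ex * flow$u + d$Ey * flow$v + d$Et)^2)
  gx <- function(m) shift_mat(m, 0, 1) - m
  gy <- function(m) shift_mat(m, 1, 0) - m
  smooth <- sum(gx(flow$u)^2 + gy(flow$u)^2 + gx(flow$v)^2 + gy(flow$v)^2)
  data + flow$alpha^2 * smooth
}

#' Overall flow magnitude
#'
#' Sums the squared modulus `u^2 + v^2` of the flow vector over all pixels
#' (per-pixel "speed" is the squared modulus; the overall magnitude is its
#' sum over the image).
#'
#' @param flow A `flow_field`.
#' @return A scalar.
#' @export
overall_flow_magnitude <- function(flow) {
  stopifnot(inherits(flow, "flow_field"))
  sum(flow$u^2 + flow$v^2)
}

#' Time-integrated flow or luminance change by eccentricity ring
#'
#' Partitions the raster into concentric eccentricity rings around fixation
#' (the raster centre) and accumulates, over pixels and frames, either the
#' squared optical-flow modulus (`metric = "flow"`, computed frame-pair by
#' frame-pair with [horn_schunck_flow()]) or the absolute luminance
#' deviation from background (`metric = "luminance"`).
#'
#' @param frames A `frame_sequence` from [render_frames()].
#' @param metric `"flow"` or `"luminance"`.
#' @param ring_edges Increasing ring boundaries in degrees; must start at 0
#'   (or below) and cover the most eccentric pixel.
#' @param alpha,n_iterations Passed to [horn_schunck_flow()] for the flow
#'   metric.
#' @return An object of class `eccentricity_profile` with `ring_edges`,
#'   per-ring `values`, per-ring `pixel_counts` and the `metric`.
#' @export
eccentricity_profile <- function(frames, metric = c("flow", "luminance"),
                                 ring_edges, alpha = 1, n_iterations = 100) {
  metric <- match.arg(metric)
  stopifnot(inherits(frames, "frame_sequence"))
  stk <- frames$frames
  n <- dim(stk)[3]
  if (metric == "flow" && n < 2) stop_domain("flow metric needs >= 2 frames")
  res <- dim(stk)[1]
  ax <- (seq_len(res) - (res + 1) / 2) * frames$pixel_pitch
  ecc <- sqrt(outer(ax^2, ax^2, `+`))
  ring_edges <- sort(ring_edges)
  if (min(ring_edges) > 0 || max(ring_edges) < max(ecc)) {
    stop_domain("`ring_edges` must cover the image (0 to max eccentricity)")
  }
  ring <- findInterval(ecc, ring_edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
  n_rings <- length(ring_edges) - 1

  per_pixel <- matrix(0, res, res)
  if (metric == "flow") {
    for (k in seq_len(n - 1)) {
      fl <- horn_schunck_flow(stk[, , k], stk[, , k + 1], alpha, n_iterations)
      per_pixel <- per_pixel + fl$u^2 + fl$v^2
    }
  } else {
    for (k in seq_len(n)) {
      per_pixel <- per_pixel + abs(stk[, , k] - frames$background_level)
    }
  }
  vals <- vapply(seq_len(n_rings), function(r) sum(per_pixel[ring == r]),
                 numeric(1))
  counts <- tabulate(ring, nbins = n_rings)
  structure(list(ring_edges = ring_edges, values = vals,
                 pixel_counts = counts, metric = metric),
            class = "eccentricity_profile")
}
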