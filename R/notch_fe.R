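# Small linear-elastic plane-stress FE model of the three-point-bend test,
# used only to regenerate the notched-beam modulus correction. Fully
# integrated 4-node bilinear quads (2x2 Gauss), rectilinear graded mesh,
# the notch realised as a zero-width slot by node splitting. Roller contact
# is replaced by pinned nodal supports and a prescribed nodal displacement:
# for a stiffness *ratio* the contact nonlinearity contributes nothing at
# first order.

# Fill [x0, x1] with steps of size at most h (at least one element).
grid_fill <- function(x0, x1, h) {
  n <- max(1L, ceiling((x1 - x0) / h - 1e-9))
  seq(x0, x1, length.out = n + 1L)
}

# Sorted unique grid lines with a tolerance, so an inserted landmark that
# coincides with a regular line does not create a sliver element.
grid_dedupe <- function(x, tol = 1e-7) {
  x <- sort(x)
  x[c(TRUE, diff(x) > tol)]
}

#' Structured quad mesh of a notched three-point-bend beam
#'
#' Rectilinear mesh of the beam (length = span plus a small overhang at
#' each end, height `W`), graded: elements of size `elem_size_fine` within
#' one width `W` of midspan (notch and load region), `elem_size_coarse`
#' elsewhere. The notch is a zero-width vertical slot of depth `a0` at
#' midspan bottom, realised by duplicating the nodes on the midspan line
#' below the notch tip so that the two faces are disconnected (and
#' traction-free).
#'
#' @param geometry A [specimen_geometry()]; its `a0` is ignored in favour
#'   of the explicit argument so one geometry can serve several notch
#'   lengths.
#' @param a0 Notch depth, mm (`0 <= a0 < W`); snapped onto the y-grid by
#'   inserting a grid line at `a0`.
#' @param elem_size_fine Approximate element size near midspan, mm.
#' @param elem_size_coarse Approximate element size elsewhere, mm.
#' @param overhang Beam extension beyond each support, mm.
#' @return Object of class `beam_mesh`: nodes (n x 2 matrix, mm),
#'   elements (ne x 4 connectivity, counter-clockwise), node index sets
#'   `left_support`, `right_support`, `load_nodes`, and bookkeeping.
#' @export
mesh_beam <- function(geometry, a0 = geometry$a0,
                      elem_size_fine = 0.05, elem_size_coarse = 0.15,
                      overhang = 0.2) {
  stopifnot(inherits(geometry, "specimen_geometry"))
  W <- geometry$W; S <- geometry$S
  if (a0 < 0 || a0 >= W) stop("a0 must lie in [0, W)")
  if (elem_size_fine <= 0 || elem_size_coarse <= 0) stop("element sizes must be positive")
  if (elem_size_fine > W) stop("element size exceeds the beam width")
  L <- S + 2 * overhang
  xc <- L / 2
  xs <- c(overhang, overhang + S)
  half_fine <- max(W, 4 * elem_size_fine)
  xb <- grid_dedupe(c(0, xs[1], xc - half_fine, xc, xc + half_fine, xs[2], L))
  xb <- xb[xb >= 0 & xb <= L]
  xg <- 0
  for (i in seq_len(length(xb) - 1)) {
    h <- if (xb[i] >= xc - half_fine - 1e-9 && xb[i + 1] <= xc + half_fine + 1e-9)
      elem_size_fine else elem_size_coarse
    xg <- c(xg, grid_fill(xb[i], xb[i + 1], h)[-1])
  }
  yg <- grid_dedupe(c(grid_fill(0, W, elem_size_fine), a0))
  yg <- yg[yg <= W + 1e-12]
  nx <- length(xg); ny <- length(yg)

  id <- matrix(seq_len(nx * ny), nx, ny)  # id[ix, iy]
  nodes <- cbind(rep(xg, times = ny), rep(yg, each = nx))

  ic <- which(abs(xg - xc) < 1e-9)[1]
  split_iy <- if (a0 > 0) which(yg < a0 - 1e-9) else integer(0)
  # duplicate the nodes on the midspan line below the notch tip; elements
  # on the right of the slot reference the duplicates
  dup_id <- integer(ny)
  if (length(split_iy)) {
    extra <- nrow(nodes) + seq_along(split_iy)
    nodes <- rbind(nodes, nodes[id[ic, split_iy], , drop = FALSE])
    dup_id[split_iy] <- extra
  }

  elems <- matrix(0L, (nx - 1) * (ny - 1), 4)
  e <- 0L
  for (iy in seq_len(ny - 1)) {
    for (ix in seq_len(nx - 1)) {
      e <- e + 1L
      n1 <- id[ix, iy]; n2 <- id[ix + 1, iy]
      n3 <- id[ix + 1, iy + 1]; n4 <- id[ix, iy + 1]
      # right-hand side of the slot: replace split left-edge nodes
      if (length(split_iy) && ix == ic) {
        if (iy %in% split_iy) n1 <- dup_id[iy]
        if ((iy + 1) %in% split_iy) n4 <- dup_id[iy + 1]
      }
      elems[e, ] <- c(n1, n2, n3, n4)
    }
  }
  area2 <- function(p) abs((p[2,1]-p[1,1])*(p[4,2]-p[1,2]) - (p[4,1]-p[1,1])*(p[2,2]-p[1,2]))
  if (any(apply(elems, 1, function(en) area2(nodes[en, ])) < 1e-12))
    stop("degenerate element in mesh")

  top_iy <- ny
  load_nodes <- id[ic, top_iy]
  structure(list(nodes = nodes, elems = elems,
                 left_support = id[which.min(abs(xg - xs[1])), 1],
                 right_support = id[which.min(abs(xg - xs[2])), 1],
                 load_nodes = load_nodes,
                 xg = xg, yg = yg, a0 = a0, geometry = geometry,
                 n_elements = nrow(elems)),
            class = "beam_mesh")
}

#' @export
print.beam_mesh <- function(x, ...) {
  cat(sprintf("beam_mesh: %d nodes, %d elements, a0 = %g mm\n",
              nrow(x$nodes), x$n_elements, x$a0))
  invisible(x)
}

# 2x2 Gauss stiffness of one bilinear quad, plane stress, thickness t.
q4_stiffness <- function(xy, E, nu, t) {
  D <- E / (1 - nu^2) * matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)
  gp <- 1 / sqrt(3) * c(-1, 1)
  Ke <- matrix(0, 8, 8)
  for (xi in gp) for (eta in gp) {
    dN <- matrix(c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta),
                   -(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4,
                 2, 4, byrow = TRUE)
    J <- dN %*% xy
    dNxy <- solve(J, dN)
    Bm <- matrix(0, 3, 8)
    Bm[1, seq(1, 8, 2)] <- dNxy[1, ]
    Bm[2, seq(2, 8, 2)] <- dNxy[2, ]
    Bm[3, seq(1, 8, 2)] <- dNxy[2, ]
    Bm[3, seq(2, 8, 2)] <- dNxy[1, ]
    Ke <- Ke + t * t(Bm) %*% D %*% Bm * det(J)
  }
  Ke
}

#' Solve the displacement-driven bend test
#'
#' Assembles the global plane-stress stiffness, pins the supports (left
#' support fully, right support vertically: rollers without the contact
#' nonlinearity), prescribes a downward displacement at the midspan top
#' node(s), and returns the bending stiffness `m` = reaction force per
#' unit prescribed displacement.
#'
#' @param mesh A [mesh_beam()] result.
#' @param E Young's modulus, MPa.
#' @param nu Poisson ratio.
#' @param prescribed_displacement Downward load-point displacement, mm
#'   (default 0.01; `m` is independent of it by linearity).
#' @return List of class `bend_solution`: `m` (N/mm), `delta`, `reaction_N`,
#'   `support_reactions_N` (left/right vertical), `u` (full dof vector),
#'   and `mesh`.
#' @export
solve_bend <- function(mesh, E, nu, prescribed_displacement = 0.01) {
  stopifnot(inherits(mesh, "beam_mesh"))
  if (E <= 0 || prescribed_displacement <= 0)
    stop("E and prescribed_displacement must be positive")
  nn <- nrow(mesh$nodes); nd <- 2L * nn
  ne <- nrow(mesh$elems)
  ii <- integer(64L * ne); jj <- integer(64L * ne); vv <- numeric(64L * ne)
  p <- 0L
  t <- mesh$geometry$B
  for (e in seq_len(ne)) {
    en <- mesh$elems[e, ]
    Ke <- q4_stiffness(mesh$nodes[en, ], E, nu, t)
    dofs <- as.vector(rbind(2L * en - 1L, 2L * en))
    idx <- p + 1:64
    ii[idx] <- rep(dofs, times = 8)
    jj[idx] <- rep(dofs, each = 8)
    vv[idx] <- as.vector(Ke)
    p <- p + 64L
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(nd, nd))

  fixed_u <- 2L * mesh$left_support - 1L
  fixed_v <- c(2L * mesh$left_support, 2L * mesh$right_support)
  load_v <- 2L * mesh$load_nodes
  pres <- c(fixed_u, fixed_v, load_v)
  pres_val <- c(rep(0, length(fixed_u) + length(fixed_v)),
                rep(-prescribed_displacement, length(load_v)))
  free <- setdiff(seq_len(nd), pres)

  u <- numeric(nd)
  u[pres] <- pres_val
  rhs <- -K[free, pres, drop = FALSE] %*% pres_val
  sol <- tryCatch(Matrix::solve(K[free, free], rhs),
                  error = function(e) stop("singular system: insufficient constraints"))
  u[free] <- as.numeric(sol)
  R <- as.numeric(K[pres, , drop = FALSE] %*% u)
  names(R) <- NULL
  reaction <- -sum(R[match(load_v, pres)])  # downward load on the beam
  structure(list(m = reaction / prescribed_displacement,
                 delta = prescribed_displacement,
                 reaction_N = reaction,
                 support_reactions_N = c(
                   left = R[match(2L * mesh$left_support, pres)],
                   right = R[match(2L * mesh$right_support, pres)]),
                 u = u, mesh = mesh),
            class = "bend_solution")
}

#' Calibrate the material modulus against a measured stiffness
#'
#' Finds `E` such that the FE model reproduces the experimental
#' load-displacement slope. The solve is linear in `E`, so a single trial
#' suffices: `E = E_trial * m_exp / m_trial`.
#'
#' @param m_exp Measured slope, N/mm.
#' @param geometry A [specimen_geometry()].
#' @param a0 Notch length of the tested specimen, mm.
#' @param E_trial Trial modulus, MPa (default 12000; the result does not
#'   depend on it).
#' @param nu Poisson ratio (default from `geometry`).
#' @param ... Passed to [mesh_beam()].
#' @return Calibrated modulus, MPa.
#' @export
calibrate_E <- function(m_exp, geometry, a0 = geometry$a0,
                        E_trial = 12000, nu = geometry$nu, ...) {
  if (m_exp <= 0) stop("m_exp must be positive")
  mesh <- mesh_beam(geometry, a0 = a0, ...)
  m_trial <- solve_bend(mesh, E_trial, nu)$m
  E_trial * m_exp / m_trial
}

#' Fit the notched-beam modulus-correction model
#'
#' For each notch length, the FE stiffness is turned into an apparent
#' flexural modulus with [flexural_modulus()]; the ratio of the apparent
#' modulus at `a0` to the apparent modulus of the un-notched beam is then
#' fitted with a second-order polynomial anchored at ratio(0) = 1. The
#' model maps a measured notched-beam flexural modulus back to the value
#' an un-notched specimen of the same material would have given
#' ([correct_modulus()]).
#'
#' @param a0_values Notch lengths, mm; at least three distinct values
#'   including 0.
#' @param slopes FE (or measured) stiffnesses at each `a0`, N/mm.
#' @param geometry A [specimen_geometry()].
#' @return Object of class `notch_correction`: list with `coeffs`
#'   (`c(1, c1, c2)` of `ratio(a0) = 1 + c1 a0 + c2 a0^2`), `a0_range`,
#'   `r2`, and the apparent-modulus table.
#' @export
fit_correction <- function(a0_values, slopes, geometry) {
  if (length(unique(a0_values)) < 3)
    stop("need at least 3 distinct a0 values")
  if (!any(a0_values == 0))
    stop("a0 values must include 0 (the un-notched anchor)")
  stopifnot(length(a0_values) == length(slopes))
  Ef <- mapply(function(a0, m) {
    g <- geometry; g$a0 <- a0
    flexural_modulus(m, g)
  }, a0_values, slopes)
  Ef0 <- mean(Ef[a0_values == 0])
  ratio <- Ef / Ef0
  y <- ratio - 1
  X <- cbind(a0_values, a0_values^2)
  fit <- stats::lm.fit(X, y)
  pred <- 1 + as.numeric(X %*% fit$coefficients)
  ss_res <- sum((ratio - pred)^2)
  ss_tot <- sum((ratio - mean(ratio))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(coeffs = c(1, unname(fit$coefficients)),
                 a0_range = range(a0_values), r2 = r2,
                 table = data.frame(a0_mm = a0_values, m_N_mm = slopes,
                                    Ef_MPa = Ef, ratio = ratio)),
            class = "notch_correction")
}

#' @export
print.notch_correction <- function(x, ...) {
  cat(sprintf(
    "notch correction: ratio(a0) = 1 + %.4g a0 + %.4g a0^2 on a0 in [%g, %g] mm (R2 = %.4f)\n",
    x$coeffs[2], x$coeffs[3], x$a0_range[1], x$a0_range[2], x$r2))
  invisible(x)
}

predict_ratio <- function(model, a0) {
  model$coeffs[1] + model$coeffs[2] * a0 + model$coeffs[3] * a0^2
}

#' Correct a measured notched-beam flexural modulus
#'
#' Divides the measured apparent flexural modulus by the fitted
#' apparent-modulus ratio at the specimen's notch length, returning the
#' modulus an un-notched specimen would have given. With no model the
#' value is returned unchanged with a loud warning; outside the fitted
#' `a0` range the model extrapolates with a warning.
#'
#' @param E_f_measured Measured flexural modulus, MPa (from
#'   [flexural_modulus()]).
#' @param a0 Notch length of the measured specimen, mm.
#' @param model A [fit_correction()] result (or `NULL`).
#' @return Corrected modulus `E`, MPa.
#' @export
correct_modulus <- function(E_f_measured, a0, model = NULL) {
  if (is.null(model)) {
    warning("no notch-correction model supplied: returning the apparent flexural modulus unchanged")
    return(E_f_measured)
  }
  stopifnot(inherits(model, "notch_correction"))
  if (a0 < model$a0_range[1] || a0 > model$a0_range[2])
    warning(sprintf("extrapolating correction: a0 = %g mm outside fitted range [%g, %g]",
                    a0, model$a0_range[1], model$a0_range[2]))
  E_f_measured / predict_ratio(model, a0)
}

#' Write / read a notch-correction model as JSON
#'
#' @param model A [fit_correction()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly (`read_correction_json` returns the model).
#' @export
write_correction_json <- function(model, path) {
  jsonlite::write_json(list(coeffs = model$coeffs,
                            a0_range = model$a0_range, r2 = model$r2),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_correction_json
#' @export
read_correction_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coeffs = as.numeric(j$coeffs),
                 a0_range = as.numeric(j$a0_range), r2 = as.numeric(j$r2),
                 table = NULL),
            class = "notch_correction")
}
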