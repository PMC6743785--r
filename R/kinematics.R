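# Surrogate vocal-tract geometry.
#
# Fixed temporomandibular joint at the origin. The palate/pharynx outline is
# the polar curve R(phi) = R0 + R1*cos(phi - phi0) (widest at phi0, i.e. the
# palatal vault). The tongue body is a circle of radius r_tongue centered at
# polar position (CL, theta) with theta = JA + CA; its constriction degree
# is the gap between the tongue surface and the outline measured radially at
# theta. The tongue tip sits at polar offset (TTL, TTA) from the tongue-body
# center and forms its own constriction against the same outline. Lip
# aperture combines the two lip verticals with a jaw contribution, and
# protrusion averages the lip horizontals. Angles increase from posterior
# (pharynx, small phi) to anterior (alveolar ridge, large phi); the negative
# x direction is anterior.

outline_radius <- function(phi, geom = geometry_constants()) {
  geom$R0 + geom$R1 * cos(phi - geom$phi0)
}

outline_radius_deriv <- function(phi, geom = geometry_constants()) {
  -geom$R1 * sin(phi - geom$phi0)
}

#' Tongue-center position in the midsagittal plane
#'
#' @param a Named articulator vector (or matrix with articulators in rows).
#' @return Numeric `c(x, y)` in cm (or a 2-row matrix). `y` is vertical
#'   (up positive); anterior is negative `x`.
#' @export
tongue_center <- function(a) {
  if (is.matrix(a)) {
    theta <- a["JA", ] + a["CA", ]
    rbind(x = a["CL", ] * cos(theta), y = a["CL", ] * sin(theta))
  } else {
    theta <- a[["JA"]] + a[["CA"]]
    c(x = a[["CL"]] * cos(theta), y = a[["CL"]] * sin(theta))
  }
}

#' Forward kinematics: articulator positions to task variables
#'
#' Computes the seven constriction task variables from the ten articulator
#' positions under the surrogate geometry. The map is smooth in `a`, and
#' deliberately redundant: jaw and lips share lip aperture, jaw and tongue
#' share the tongue-body constriction. Positions outside the articulator
#' range box are clamped (with a warning) before evaluation, mirroring the
#' plant's own clamping.
#'
#' @param a Named numeric vector of 10 articulator positions (order per
#'   [articulator_inventory()]), or a 10 x n matrix (articulators in rows)
#'   for vectorized evaluation.
#' @param geom Geometry constants, see [geometry_constants()].
#' @param warn_clamp Warn when input had to be clamped into the range box.
#' @return Named numeric vector of 7 task variables (or a 7 x n matrix).
#' @export
forward_kinematics <- function(a, geom = geometry_constants(), warn_clamp = TRUE) {
  vec_in <- !is.matrix(a)
  A <- if (vec_in) matrix(a, ncol = 1, dimnames = list(articulator_inventory(), NULL)) else a
  if (is.null(rownames(A))) rownames(A) <- articulator_inventory()
  box <- articulator_range_box()
  lo <- box["lo", rownames(A)]; hi <- box["hi", rownames(A)]
  clamped <- A < lo | A > hi
  if (any(clamped)) {
    if (warn_clamp) {
      warn(paste0("articulator position(s) outside the range box clamped: ",
                  paste(unique(rownames(A)[which(clamped, arr.ind = TRUE)[, 1]]),
                        collapse = ", ")))
    }
    A <- pmin(pmax(A, lo), hi)
  }

  theta <- A["JA", ] + A["CA", ]
  cl <- A["CL", ]
  tbcl <- theta
  tbcd <- outline_radius(theta, geom) - cl - geom$r_tongue

  phi_tip <- theta + A["TTA", ]
  tip_x <- cl * cos(theta) + A["TTL", ] * cos(phi_tip)
  tip_y <- cl * sin(theta) + A["TTL", ] * sin(phi_tip)
  rho <- sqrt(tip_x^2 + tip_y^2)
  ang <- atan2(tip_y, tip_x)
  ttcl <- ang
  ttcd <- outline_radius(ang, geom) - rho

  la <- A["ULV", ] - A["LLV", ] - geom$kappa_jaw * (A["JA", ] - geom$ja_ref)
  pro <- (A["ULH", ] + A["LLH", ]) / 2
  vel <- A["VEL", ]

  X <- rbind(LA = la, PRO = pro, TBCD = tbcd, TBCL = tbcl,
             TTCD = ttcd, TTCL = ttcl, VEL = vel)
  if (vec_in) X[, 1] else X
}

#' Jacobian of the forward kinematics
#'
#' `jacobian()` returns the 7 x 10 matrix `J = df/da` of the task map with
#' respect to articulator positions, computed analytically by default (the
#' surrogate geometry differentiates in closed form) or by central finite
#' differences with step `1e-6`. `jacobian_dot()` returns the time
#' derivative of `J` along articulator velocities `a_dot`, evaluated as the
#' directional derivative `dJ/dt = sum_k (dJ/da_k) a_dot_k` via a central
#' difference of the analytic Jacobian along `a_dot`.
#'
#' @param a Named articulator position vector (10).
#' @param method `"analytic"` (default) or `"fd"` (central differences).
#' @param geom Geometry constants.
#' @param a_dot Articulator velocity vector (10).
#' @return A 7 x 10 matrix with task rows and articulator columns.
#' @export
jacobian <- function(a, method = c("analytic", "fd"), geom = geometry_constants()) {
  method <- match.arg(method)
  arts <- articulator_inventory()
  a <- a[arts]
  if (method == "fd") {
    h <- 1e-6
    J <- matrix(0, 7, 10, dimnames = list(task_inventory(), arts))
    for (j in seq_along(arts)) {
      ap <- a; am <- a
      ap[j] <- ap[j] + h; am[j] <- am[j] - h
      J[, j] <- (forward_kinematics(ap, geom, warn_clamp = FALSE) -
                   forward_kinematics(am, geom, warn_clamp = FALSE)) / (2 * h)
    }
    return(J)
  }

  J <- matrix(0, 7, 10, dimnames = list(task_inventory(), arts))
  theta <- a[["JA"]] + a[["CA"]]
  cl <- a[["CL"]]

  # lips
  J["LA", "ULV"] <- 1; J["LA", "LLV"] <- -1; J["LA", "JA"] <- -geom$kappa_jaw
  J["PRO", "ULH"] <- 0.5; J["PRO", "LLH"] <- 0.5
  J["VEL", "VEL"] <- 1

  # tongue body
  rp <- outline_radius_deriv(theta, geom)
  J["TBCD", "JA"] <- rp; J["TBCD", "CA"] <- rp; J["TBCD", "CL"] <- -1
  J["TBCL", "JA"] <- 1; J["TBCL", "CA"] <- 1

  # tongue tip: position of the tip point and its partials
  phi_tip <- theta + a[["TTA"]]
  ttl <- a[["TTL"]]
  x <- cl * cos(theta) + ttl * cos(phi_tip)
  y <- cl * sin(theta) + ttl * sin(phi_tip)
  rho2 <- x^2 + y^2
  rho <- sqrt(rho2)
  # partials of (x, y) wrt (JA, CA, CL, TTA, TTL)
  dx <- c(JA = -y, CA = -y, CL = cos(theta),
          TTA = -ttl * sin(phi_tip), TTL = cos(phi_tip))
  dy <- c(JA = x, CA = x, CL = sin(theta),
          TTA = ttl * cos(phi_tip), TTL = sin(phi_tip))
  dang <- (x * dy - y * dx) / rho2
  drho <- (x * dx + y * dy) / rho
  ang <- atan2(y, x)
  rp_tip <- outline_radius_deriv(ang, geom)
  for (nm in names(dx)) {
    J["TTCL", nm] <- dang[[nm]]
    J["TTCD", nm] <- rp_tip * dang[[nm]] - drho[[nm]]
  }
  J
}

#' @rdname jacobian
#' @export
jacobian_dot <- function(a, a_dot, geom = geometry_constants()) {
  arts <- articulator_inventory()
  a <- a[arts]; a_dot <- a_dot[arts]
  nrm <- max(abs(a_dot))
  if (!is.finite(nrm)) abort("non-finite articulator velocity in jacobian_dot()")
  if (nrm == 0) {
    return(matrix(0, 7, 10, dimnames = list(task_inventory(), arts)))
  }
  h <- 1e-6 / max(1, nrm)
  (jacobian(a + h * a_dot, geom = geom) - jacobian(a - h * a_dot, geom = geom)) / (2 * h)
}

#' Weighted Jacobian pseudoinverse
#'
#' Computes `J* = W^-1 Ja' (Ja W^-1 Ja' + eps I)^-1` on the rows `Ja` of `J`
#' selected by the active-task mask, and maps the result back into a full
#' 10 x 7 matrix with zero columns for inactive tasks. `W` is a symmetric
#' positive-definite articulator weighting (identity by default: all
#' articulators share task burden equally); `eps` is a small Tikhonov term
#' that regularizes near-singular task row sets.
#'
#' @param J Task Jacobian (7 x 10).
#' @param W Articulator weight matrix (10 x 10), symmetric positive definite.
#' @param mask Logical length-7 vector of active tasks (or integer row indices).
#' @param eps Tikhonov regularization added to `Ja W^-1 Ja'`.
#' @return A 10 x 7 matrix `J*` (articulators x tasks).
#' @export
weighted_pseudoinverse <- function(J, W = diag(ncol(J)), mask = rep(TRUE, nrow(J)),
                                   eps = 1e-8) {
  if (is.logical(mask)) mask <- which(mask)
  Jstar <- matrix(0, ncol(J), nrow(J), dimnames = list(colnames(J), rownames(J)))
  if (length(mask) == 0) return(Jstar)
  Ja <- J[mask, , drop = FALSE]
  Winv_Jt <- solve(W, t(Ja))
  A <- Ja %*% Winv_Jt + eps * diag(length(mask))
  rc <- rcond(A)
  if (!is.finite(rc) || rc < 1e-12) {
    rows <- rownames(J)[mask]
    abort(paste0("task Jacobian rows are rank deficient beyond regularization: ",
                 paste(rows, collapse = ", ")))
  }
  Jstar[, mask] <- Winv_Jt %*% solve(A)
  Jstar
}

#' Articulatory state feedback control law
#'
#' Inverse-kinematics control: converts a commanded task acceleration into
#' articulator accelerations through the weighted Jacobian pseudoinverse,
#'
#' \deqn{\ddot a = J^*(\tilde a)\,\ddot x - J^*(\tilde a)\,\dot J(\tilde a,
#' \dot{\tilde a})\,\dot{\tilde a} + (I - J^* J_a)\,n(\tilde a,
#' \dot{\tilde a}),}
#'
#' where the final term is an optional null-space attractor `n = -k_n (a -
#' a0) - b_n a_dot` toward the neutral posture that bounds drift of
#' redundant, uncontrolled degrees of freedom without disturbing active
#' tasks. For a full-row-rank active Jacobian the commanded task
#' acceleration is achieved exactly (up to the Tikhonov term): `Ja %*% a_ddot
#' + Jdot_a %*% a_dot = x_ddot` on active tasks.
#'
#' @param x_ddot Commanded task accelerations (length 7; zero on inactive tasks).
#' @param est List with `a` (estimated articulator positions) and `a_dot`
#'   (estimated velocities).
#' @param mask Logical length-7 active-task mask.
#' @param W Articulator weight matrix (identity default).
#' @param null_attractor List with `on` (logical), `k` (1/s^2) and `b`
#'   (1/s); defaults from [sfc_config()].
#' @param geom Geometry constants.
#' @param eps Pseudoinverse regularization.
#' @return Named length-10 vector of commanded articulator accelerations.
#' @export
articulatory_command <- function(x_ddot, est, mask = rep(TRUE, 7),
                                 W = diag(10),
                                 null_attractor = list(on = TRUE, k = 10,
                                                       b = 2 * sqrt(10)),
                                 geom = geometry_constants(), eps = 1e-8) {
  a <- est$a; a_dot <- est$a_dot
  if (!all(is.finite(x_ddot)) || !all(is.finite(a)) || !all(is.finite(a_dot))) {
    abort("non-finite input to articulatory_command()")
  }
  arts <- articulator_inventory()
  J <- jacobian(a, geom = geom)
  Jstar <- weighted_pseudoinverse(J, W = W, mask = mask, eps = eps)
  if (any(mask)) {
    Jd <- jacobian_dot(a, a_dot, geom = geom)
    a_ddot <- drop(Jstar %*% x_ddot) - drop(Jstar %*% (Jd %*% a_dot))
    Nproj <- diag(10) - Jstar[, mask, drop = FALSE] %*% J[mask, , drop = FALSE]
  } else {
    a_ddot <- rep(0, 10)
    Nproj <- diag(10)
  }
  if (isTRUE(null_attractor$on)) {
    n <- -null_attractor$k * (a - neutral_posture()[arts]) - null_attractor$b * a_dot
    a_ddot <- a_ddot + drop(Nproj %*% n)
  }
  setNames(a_ddot, arts)
}
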