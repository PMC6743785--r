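#' Task and articulator inventories
#'
#' The vocal-tract model controls seven constriction task variables through
#' ten kinematic articulators. Task variables are functional measures of the
#' vocal tract (apertures/degrees in cm, locations in radians); articulators
#' are the model's independently movable degrees of freedom.
#'
#' Task inventory (fixed order):
#' \describe{
#'   \item{LA}{lip aperture (cm)}
#'   \item{PRO}{lip protrusion (cm)}
#'   \item{TBCD}{tongue-body constriction degree (cm)}
#'   \item{TBCL}{tongue-body constriction location (rad)}
#'   \item{TTCD}{tongue-tip constriction degree (cm)}
#'   \item{TTCL}{tongue-tip constriction location (rad)}
#'   \item{VEL}{velic aperture (cm)}
#' }
#'
#' Articulator inventory (fixed order): JA jaw angle (rad), CA condyle angle
#' (rad), CL condyle length (cm), TTA tongue-tip angle (rad), TTL tongue-tip
#' length (cm), ULV/LLV upper/lower lip vertical (cm), ULH/LLH upper/lower
#' lip horizontal (cm), VEL velum (cm).
#'
#' @return Character vector of variable names, in canonical order.
#' @export
task_inventory <- function() {
  c("LA", "PRO", "TBCD", "TBCL", "TTCD", "TTCL", "VEL")
}

#' @rdname task_inventory
#' @export
articulator_inventory <- function() {
  c("JA", "CA", "CL", "TTA", "TTL", "ULV", "LLV", "ULH", "LLH", "VEL")
}

#' Articulator range box
#'
#' Hard kinematic limits for each articulator. The plant clamps positions to
#' this box during integration (with velocity zeroed at the boundary), which
#' keeps the surrogate geometry non-degenerate; the babbling generator and
#' the forward-model trainer sample inside the same box.
#'
#' @return A 2 x 10 matrix with rows `lo` and `hi`, columns named per
#'   [articulator_inventory()].
#' @export
articulator_range_box <- function() {
  box <- rbind(
    lo = c(JA = -0.3, CA = 0.8, CL = 1.8, TTA = -0.5, TTL = 1.2,
           ULV = -0.2, LLV = -0.9, ULH = -0.5, LLH = -0.5, VEL = -0.2),
    hi = c(JA = 0.5, CA = 1.9, CL = 4.2, TTA = 1.0, TTL = 3.2,
           ULV = 0.9, LLV = 0.2, ULH = 0.5, LLH = 0.5, VEL = 0.8)
  )
  box
}

#' Neutral articulator posture
#'
#' Rest configuration of the surrogate vocal tract. The uncontrolled
#' (null-space) attractor in the articulatory control law pulls toward this
#' posture, and simulations start from it at rest. At neutral the tongue
#' body constriction is wide (TBCD about 1.09 cm) and the lips are about
#' 1 cm apart.
#'
#' @return Named numeric vector of 10 articulator positions.
#' @export
neutral_posture <- function() {
  c(JA = 0.1, CA = 1.3, CL = 2.7, TTA = 0.15, TTL = 2.2,
    ULV = 0.5, LLV = -0.5, ULH = 0.0, LLH = 0.0, VEL = 0.0)
}

#' Surrogate vocal-tract geometry constants
#'
#' Parameters of the closed-form constriction geometry used in place of a
#' full articulatory synthesizer: a fixed temporomandibular joint at the
#' origin, a palate/pharynx outline at radius `R(phi) = R0 + R1*cos(phi -
#' phi0)`, a circular tongue body of radius `r_tongue` whose center sits at
#' polar position (CL, JA + CA), a tongue tip at polar offset (TTL, TTA)
#' from the tongue-body center, and a lip aperture that closes with jaw
#' angle at rate `kappa_jaw` around reference angle `ja_ref`.
#'
#' @return Named list of geometry constants (cm and radians).
#' @export
geometry_constants <- function() {
  list(
    R0 = 5.0,          # mean outline radius (cm)
    R1 = 0.8,          # outline eccentricity (cm)
    phi0 = pi / 2,     # angle of widest outline point (rad)
    r_tongue = 2.0,    # tongue-body radius (cm)
    kappa_jaw = 2.0,   # jaw contribution to lip aperture (cm/rad)
    ja_ref = 0.1       # jaw angle at which lips alone set LA (rad)
  )
}

# number of somatosensory channels: articulator positions + velocities
n_somat_channels <- function() 2L * length(articulator_inventory())
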