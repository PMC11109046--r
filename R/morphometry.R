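#' Perpendicular distance from a point to a line
#'
#' Unsigned perpendicular distance from point `p` to the infinite line
#' through `a` and `b`, computed as `|cross(b - a, p - a)| / |b - a|`.
#' This operationalises every "vertical distance of X to the connection of
#' Y and Z" measurement: concavity depths, body heights and body widths.
#'
#' @param p,a,b Numeric length-2 vectors (x, y) in millimetres.
#' @param names Optional character vector of length 3 naming the landmarks,
#'   used in error messages.
#' @return Distance in millimetres (scalar, >= 0).
#' @export
point_line_distance <- function(p, a, b, names = NULL) {
  ab <- b - a
  nrm <- sqrt(sum(ab^2))
  if (nrm == 0) {
    who <- if (is.null(names)) "'a' and 'b'" else
      paste0("'", names[2], "' and '", names[3], "'")
    stop("degenerate line: landmarks ", who, " coincide", call. = FALSE)
  }
  unname(abs(ab[1] * (p[2] - a[2]) - ab[2] * (p[1] - a[1])) / nrm)
}

# signed variant: positive when p lies on the same side of line(a,b) as ref
signed_point_line_distance <- function(p, a, b, ref) {
  ab <- b - a
  nrm <- sqrt(sum(ab^2))
  cr <- function(q) ab[1] * (q[2] - a[2]) - ab[2] * (q[1] - a[1])
  d <- unname(cr(p) / nrm)
  if (cr(ref) < 0) -d else d
}

#' Angle at a vertex between two rays
#'
#' Unsigned angle in degrees between rays `vertex -> q1` and
#' `vertex -> q2`: the arc-cosine of the normalised dot product,
#' evaluated in the numerically stable `atan2(|cross|, dot)` form (exact
#' near 0 and 180 degrees, where the plain arc-cosine loses half the
#' machine precision). Used for the antero-superior angles at C2p, C3lp
#' and C4lp, which approach 0 for flat borders.
#'
#' @param vertex,q1,q2 Numeric length-2 vectors (x, y).
#' @param names Optional character vector of length 3 naming the landmarks.
#' @return Angle in degrees, in \[0, 180\].
#' @export
vertex_angle <- function(vertex, q1, q2, names = NULL) {
  v1 <- q1 - vertex
  v2 <- q2 - vertex
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) {
    who <- if (is.null(names)) "a ray endpoint" else
      paste0("'", names[if (n1 == 0) 2 else 3], "'")
    stop("zero-length ray: ", who, " coincides with the vertex",
         call. = FALSE)
  }
  cr <- v1[1] * v2[2] - v1[2] * v2[1]
  unname(atan2(abs(cr), sum(v1 * v2)) * 180 / pi)
}

euclid <- function(p, q) unname(sqrt(sum((p - q)^2)))

# Features for one subject's 15 x 2 landmark matrix.
features_one <- function(pts, subject_id = "?", signed_depths = FALSE) {
  g <- function(lab) pts[lab, ]
  pld <- function(p, a, b) {
    point_line_distance(g(p), g(a), g(b), names = c(p, a, b))
  }

  D2 <- pld("C2d", "C2a", "C2p")
  D3 <- pld("C3d", "C3la", "C3lp")
  D4 <- pld("C4d", "C4la", "C4lp")
  AH3 <- pld("C3ua", "C3la", "C3lp"); AH4 <- pld("C4ua", "C4la", "C4lp")
  PH3 <- pld("C3up", "C3la", "C3lp"); PH4 <- pld("C4up", "C4la", "C4lp")
  UW3 <- pld("C3ua", "C3up", "C3lp"); UW4 <- pld("C4ua", "C4up", "C4lp")
  LW3 <- pld("C3la", "C3up", "C3lp"); LW4 <- pld("C4la", "C4up", "C4lp")

  for (nm in c("AH3", "AH4", "UW3", "UW4", "LW3", "LW4")) {
    if (get(nm) == 0) {
      stop("subject '", subject_id, "': ", nm,
           " is zero, ratio undefined", call. = FALSE)
    }
  }

  fv <- c(
    D2 = D2, D3 = D3, D4 = D4, AH3 = AH3, AH4 = AH4, PH3 = PH3, PH4 = PH4,
    UW3 = UW3, UW4 = UW4, LW3 = LW3, LW4 = LW4,
    D3_AH3 = D3 / AH3, D4_AH4 = D4 / AH4,
    PH3_UW3 = PH3 / UW3, PH4_UW4 = PH4 / UW4,
    PH3_LW3 = PH3 / LW3, PH4_LW4 = PH4 / LW4,
    ang2 = vertex_angle(g("C2p"), g("C2d"), g("C2a"),
                        names = c("C2p", "C2d", "C2a")),
    ang3 = vertex_angle(g("C3lp"), g("C3d"), g("C3la"),
                        names = c("C3lp", "C3d", "C3la")),
    ang4 = vertex_angle(g("C4lp"), g("C4d"), g("C4la"),
                        names = c("C4lp", "C4d", "C4la")),
    C2a_C3ua = euclid(g("C2a"), g("C3ua")),
    C2p_C3up = euclid(g("C2p"), g("C3up")),
    C3la_C4ua = euclid(g("C3la"), g("C4ua")),
    C3lp_C4up = euclid(g("C3lp"), g("C4up"))
  )

  if (signed_depths) {
    # diagnostic only: positive when d bulges toward the vertebral body
    # (same side as ua; for C2, the side away from C3up)
    ref2 <- g("C2a") + (g("C2a") - g("C3up"))
    fv <- c(fv,
      D2_signed = signed_point_line_distance(g("C2d"), g("C2a"), g("C2p"),
                                             ref2),
      D3_signed = signed_point_line_distance(g("C3d"), g("C3la"), g("C3lp"),
                                             g("C3ua")),
      D4_signed = signed_point_line_distance(g("C4d"), g("C4la"), g("C4lp"),
                                             g("C4ua")))
  }
  fv
}

#' Extract the 24 morphometric parameters
#'
#' Computes, for every subject in a cohort, the morphometric feature
#' vector: concavity depths `D2`, `D3`, `D4` (perpendicular distance of
#' the lower border's most superior point `d` to the line through the
#' border endpoints; ~0 for a flat border), anterior/posterior body
#' heights `AH3/4`, `PH3/4` (distances of `ua`/`up` to the lower-border
#' line), upper/lower body widths `UW3/4`, `LW3/4` (distances of `ua`/`la`
#' to the posterior-border line `up`--`lp`), the six ratios
#' `D3_AH3`, `D4_AH4`, `PH3_UW3`, `PH4_UW4`, `PH3_LW3`, `PH4_LW4`, the
#' antero-superior angles `ang2`, `ang3`, `ang4` (vertex at `C2p`,
#' `C3lp`, `C4lp`) and the four inter-vertebral distances `C2a_C3ua`,
#' `C2p_C3up`, `C3la_C4ua`, `C3lp_C4up`. Chronological age is copied from
#' the record.
#'
#' All quantities are invariant under rigid motion and reflection of the
#' coordinates, and lengths scale linearly (ratios and angles are
#' unchanged) under uniform scaling.
#'
#' @param x A [cvm_cohort], or a single 15 x 2 landmark matrix with rows
#'   named by [cvm_landmark_labels].
#' @param signed_depths If `TRUE`, additionally report signed concavity
#'   depths `D2_signed`, `D3_signed`, `D4_signed` (positive when `d` is
#'   displaced toward the vertebral body). Diagnostic only; never used by
#'   the staging models.
#' @return A data frame of class `cvm_features` with columns `subject_id`,
#'   `age`, `true_stage` and the 24 parameters (plus signed depths if
#'   requested). For a single matrix, a named numeric vector.
#' @export
extract_features <- function(x, signed_depths = FALSE) {
  if (is.matrix(x)) {
    if (!all(cvm_landmark_labels %in% rownames(x))) {
      stop("landmark matrix must have all 15 labelled rows", call. = FALSE)
    }
    return(features_one(x[cvm_landmark_labels, , drop = FALSE],
                        signed_depths = signed_depths))
  }
  stopifnot(inherits(x, "cvm_cohort"))
  rows <- lapply(x$subjects$subject_id, function(id) {
    features_one(subject_points_from(x$coords, id), subject_id = id,
                 signed_depths = signed_depths)
  })
  out <- cbind(
    x$subjects[, c("subject_id", "age", "true_stage")],
    as.data.frame(do.call(rbind, rows))
  )
  rownames(out) <- NULL
  structure(out, class = c("cvm_features", "data.frame"))
}
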