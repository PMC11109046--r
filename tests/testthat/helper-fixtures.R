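# Fixtures built in code: no data files needed.

# Axis-aligned 12 x 10 mm vertebral bodies with flat borders, d at the
# lower-border midpoint, 3 mm inter-body gaps. Known geometry: all
# depths 0, AH = PH = 10, UW = LW = 12, antero-superior angles 0,
# inter-vertebral point distances 3.
rect_points <- function(width = 12, height = 10, gap = 3) {
  quad <- function(y0) rbind(
    la = c(width, y0), lp = c(0, y0),
    ua = c(width, y0 + height), up = c(0, y0 + height),
    um = c(width / 2, y0 + height), d = c(width / 2, y0)
  )
  c4 <- quad(0)
  c3 <- quad(height + gap)
  y2 <- 2 * (height + gap)
  m <- rbind(
    C2a = c(width, y2), C2p = c(0, y2), C2d = c(width / 2, y2),
    C3la = c3["la", ], C3lp = c3["lp", ], C3ua = c3["ua", ],
    C3up = c3["up", ], C3um = c3["um", ], C3d = c3["d", ],
    C4la = c4["la", ], C4lp = c4["lp", ], C4ua = c4["ua", ],
    C4up = c4["up", ], C4um = c4["um", ], C4d = c4["d", ]
  )
  colnames(m) <- c("x", "y")
  m
}

points_to_coords <- function(pts, subject_id = "s1", age = 10,
                             true_stage = NA_integer_) {
  data.frame(subject_id = subject_id, age = age, true_stage = true_stage,
             point_label = rownames(pts), x_mm = pts[, 1], y_mm = pts[, 2],
             stringsAsFactors = FALSE)
}

rect_cohort <- function(...) {
  cvm_cohort(points_to_coords(rect_points(), ...))
}

# random anatomically plausible landmark matrix (upright orientation)
random_subject_points <- function() {
  tpl <- stage_template()
  stage <- sample(1:4, 1)
  co <- simulate_landmarks(n_per_stage = 1, seed = sample.int(1e6, 1),
                           template = tpl)
  subject_points(co, co$subjects$subject_id[stage])
}

rigid_transform <- function(pts, angle_deg, shift) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  sweep(pts %*% t(R), 2, shift, "+")
}

# independent geometric oracle: distance from p to line(a, b) by numeric
# minimisation of |p - (a + t (b - a))| over t
pld_oracle <- function(p, a, b) {
  f <- function(t) sqrt(sum((p - (a + t * (b - a)))^2))
  # coarse bracket then high-precision 1-d minimisation
  tg <- seq(-100, 100, length.out = 2001)
  t0 <- tg[which.min(vapply(tg, f, 0))]
  stats::optimize(f, c(t0 - 1, t0 + 1), tol = 1e-12)$objective
}

# independent angle oracle: clipped arc-cosine of the normalised dot
# product (accurate to ~1e-6 degrees near 0/180)
angle_oracle <- function(v, q1, q2) {
  u <- q1 - v
  w <- q2 - v
  cosang <- sum(u * w) / sqrt(sum(u^2) * sum(w^2))
  acos(min(1, max(-1, cosang))) * 180 / pi
}
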