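#' Recognised landmark labels
#'
#' The 15 cephalometric landmarks used for CVM staging, on the second to
#' fourth cervical vertebrae. C2 contributes only its lower border (`a`,
#' `p`, `d`); C3 and C4 contribute the four body corners (`la`, `lp`, `ua`,
#' `up`), the upper-border midpoint (`um`) and the most superior point of
#' the lower border (`d`).
#'
#' @format Character vector of length 15.
#' @export
cvm_landmark_labels <- c(
  "C2a", "C2p", "C2d",
  "C3la", "C3lp", "C3ua", "C3up", "C3um", "C3d",
  "C4la", "C4lp", "C4ua", "C4up", "C4um", "C4d"
)

#' Morphometric feature names
#'
#' Names of the 24 morphometric parameters computed by
#' [extract_features()]: concavity depths (D2--D4), anterior/posterior body
#' heights (AH, PH), upper/lower body widths (UW, LW), six dimensionless
#' ratios, three antero-superior angles (ang2--ang4, degrees) and four
#' inter-vertebral point distances. All lengths are in millimetres.
#'
#' @format Character vector of length 24.
#' @export
cvm_feature_names <- c(
  "D2", "D3", "D4", "AH3", "AH4", "PH3", "PH4",
  "UW3", "UW4", "LW3", "LW4",
  "D3_AH3", "D4_AH4", "PH3_UW3", "PH4_UW4", "PH3_LW3", "PH4_LW4",
  "ang2", "ang3", "ang4",
  "C2a_C3ua", "C2p_C3up", "C3la_C4ua", "C3lp_C4up"
)

#' Assemble a cohort of landmarked subjects
#'
#' A `cvm_cohort` holds, for each subject, an id, chronological age (years),
#' an optional true maturation stage and the 15 landmark coordinates in the
#' internal convention: y increases upward ("superior"), units millimetres.
#'
#' @param coords Long data frame with columns `subject_id`, `age`,
#'   `point_label`, `x_mm`, `y_mm` and optionally `true_stage`.
#' @param provenance Free-text provenance string carried along with the
#'   cohort (e.g. `"synthetic, seed=1"`).
#' @param age_range Plausibility window for age in years; ages outside it
#'   are rejected.
#' @return An object of class `cvm_cohort`: a list with elements `subjects`
#'   (data frame: `subject_id`, `age`, `true_stage`), `coords` (long data
#'   frame of coordinates) and `provenance`.
#' @export
cvm_cohort <- function(coords, provenance = "", age_range = c(4, 25)) {
  required <- c("subject_id", "age", "point_label", "x_mm", "y_mm")
  missing_cols <- setdiff(required, names(coords))
  if (length(missing_cols)) {
    stop("landmark table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(coords) == 0) {
    return(structure(
      list(subjects = data.frame(subject_id = character(), age = numeric(),
                                 true_stage = integer(),
                                 stringsAsFactors = FALSE),
           coords = data.frame(subject_id = character(), age = numeric(),
                               true_stage = integer(),
                               point_label = character(),
                               x_mm = numeric(), y_mm = numeric(),
                               stringsAsFactors = FALSE),
           provenance = provenance),
      class = "cvm_cohort"
    ))
  }
  coords$subject_id <- as.character(coords$subject_id)
  coords$point_label <- as.character(coords$point_label)
  if (!("true_stage" %in% names(coords))) coords$true_stage <- NA_integer_

  bad_label <- setdiff(unique(coords$point_label), cvm_landmark_labels)
  if (length(bad_label)) {
    stop("unrecognised landmark label(s): ", paste(bad_label, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("age", "x_mm", "y_mm")) {
    if (!is.numeric(coords[[col]]) || anyNA(coords[[col]]) ||
        any(!is.finite(coords[[col]]))) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(coords[[col]]))))
      stop("non-finite or non-numeric '", col, "' at row(s): ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }

  ids <- unique(coords$subject_id)
  subjects <- data.frame(
    subject_id = ids,
    age = vapply(ids, function(i) coords$age[coords$subject_id == i][1], 0),
    true_stage = vapply(ids, function(i) {
      s <- coords$true_stage[coords$subject_id == i][1]
      if (is.na(s)) NA_integer_ else as.integer(s)
    }, 1L),
    stringsAsFactors = FALSE, row.names = NULL
  )

  for (i in ids) {
    lab <- coords$point_label[coords$subject_id == i]
    dup <- unique(lab[duplicated(lab)])
    if (length(dup)) {
      stop("subject '", i, "': duplicate landmark label(s): ",
           paste(dup, collapse = ", "), call. = FALSE)
    }
    mis <- setdiff(cvm_landmark_labels, lab)
    if (length(mis)) {
      stop("subject '", i, "': missing landmark label(s): ",
           paste(mis, collapse = ", "), call. = FALSE)
    }
  }
  bad_age <- subjects$subject_id[subjects$age < age_range[1] |
                                 subjects$age > age_range[2]]
  if (length(bad_age)) {
    stop("age outside plausibility window [", age_range[1], ", ",
         age_range[2], "] years for subject(s): ",
         paste(head(bad_age, 5), collapse = ", "), call. = FALSE)
  }
  bad_stage <- subjects$subject_id[!is.na(subjects$true_stage) &
                                   !(subjects$true_stage %in% 1:4)]
  if (length(bad_stage)) {
    stop("true_stage must be in {1,2,3,4}; offending subject(s): ",
         paste(head(bad_stage, 5), collapse = ", "), call. = FALSE)
  }

  # anatomical sanity: upper-border points superior to lower-border points
  for (i in ids) {
    pts <- subject_points_from(coords, i)
    for (v in c("C3", "C4")) {
      if (pts[paste0(v, "ua"), 2] <= pts[paste0(v, "la"), 2] ||
          pts[paste0(v, "up"), 2] <= pts[paste0(v, "lp"), 2]) {
        stop("subject '", i, "': ", v,
             " upper-border points are not superior to lower-border points",
             " (check the axis convention)", call. = FALSE)
      }
    }
  }

  structure(
    list(subjects = subjects,
         coords = coords[, c("subject_id", "age", "true_stage",
                             "point_label", "x_mm", "y_mm")],
         provenance = provenance),
    class = "cvm_cohort"
  )
}

subject_points_from <- function(coords, id) {
  rows <- coords[coords$subject_id == id, ]
  m <- as.matrix(rows[, c("x_mm", "y_mm")])
  rownames(m) <- rows$point_label
  m[cvm_landmark_labels, , drop = FALSE]
}

#' Extract one subject's landmark matrix
#'
#' @param cohort A [cvm_cohort] object.
#' @param subject_id Subject identifier.
#' @return A 15 x 2 matrix of (x, y) coordinates in millimetres, rows named
#'   by landmark label.
#' @export
subject_points <- function(cohort, subject_id) {
  stopifnot(inherits(cohort, "cvm_cohort"))
  if (!subject_id %in% cohort$subjects$subject_id) {
    stop("unknown subject_id: ", subject_id, call. = FALSE)
  }
  subject_points_from(cohort$coords, subject_id)
}

#' @export
print.cvm_cohort <- function(x, ...) {
  cat("CVM landmark cohort:", nrow(x$subjects), "subject(s)\n")
  cat("  age range:", sprintf("%.1f-%.1f years", min(x$subjects$age),
                              max(x$subjects$age)), "\n")
  st <- x$subjects$true_stage
  if (any(!is.na(st))) {
    cat("  true stages:", paste(sprintf("iCS%d: %d", 1:4,
        tabulate(st[!is.na(st)], 4)), collapse = ", "), "\n")
  }
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Read a landmark coordinate table
#'
#' Reads a subject landmark table from CSV. The canonical layout is long
#' format with columns `subject_id`, `age`, `point_label`, `x_mm`, `y_mm`
#' (optionally `true_stage`); a wide layout with one row per subject and
#' coordinate columns `<label>_x` / `<label>_y` is also accepted.
#'
#' The `convention` flag declares the direction of the y axis in the file.
#' Digitisation tools that use image pixel coordinates (e.g. ImageJ
#' exports) count y downward; such files are read with
#' `convention = "image"` and have y negated on input so that internally y
#' always increases toward superior. All extracted morphometric quantities
#' are invariant under this reflection.
#'
#' @param path CSV file path.
#' @param convention `"math"` (y increases upward, default) or `"image"`
#'   (y increases downward; y is negated on input).
#' @param age_range Plausibility window for age in years.
#' @return A [cvm_cohort].
#' @export
read_landmark_table <- function(path, convention = c("math", "image"),
                                age_range = c(4, 25)) {
  convention <- match.arg(convention)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if ("point_label" %in% names(raw)) {
    coords <- raw
  } else {
    # wide layout: one row per subject, columns C2a_x, C2a_y, ...
    need <- as.vector(rbind(paste0(cvm_landmark_labels, "_x"),
                            paste0(cvm_landmark_labels, "_y")))
    mis <- setdiff(c("subject_id", "age", need), names(raw))
    if (length(mis)) {
      stop("wide landmark table is missing column(s): ",
           paste(head(mis, 6), collapse = ", "), call. = FALSE)
    }
    coords <- do.call(rbind, lapply(seq_len(nrow(raw)), function(r) {
      data.frame(
        subject_id = raw$subject_id[r],
        age = raw$age[r],
        true_stage = if ("true_stage" %in% names(raw))
          raw$true_stage[r] else NA_integer_,
        point_label = cvm_landmark_labels,
        x_mm = as.numeric(raw[r, paste0(cvm_landmark_labels, "_x")]),
        y_mm = as.numeric(raw[r, paste0(cvm_landmark_labels, "_y")]),
        stringsAsFactors = FALSE
      )
    }))
  }
  for (col in c("x_mm", "y_mm", "age")) {
    v <- suppressWarnings(as.numeric(coords[[col]]))
    if (anyNA(v)) {
      stop("non-numeric '", col, "' at data row(s): ",
           paste(head(which(is.na(v)), 5), collapse = ", "), call. = FALSE)
    }
    coords[[col]] <- v
  }
  if (convention == "image") coords$y_mm <- -coords$y_mm
  cvm_cohort(coords, provenance = paste0("file:", path),
             age_range = age_range)
}

#' Write a landmark coordinate table
#'
#' Writes the canonical long-format CSV (`subject_id`, `age`,
#' `true_stage`, `point_label`, `x_mm`, `y_mm`) with coordinates rounded to
#' 6 decimals; [read_landmark_table()] on the result reproduces the cohort
#' coordinates to that precision.
#'
#' @param cohort A [cvm_cohort].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmark_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "cvm_cohort"))
  out <- cohort$coords
  out$x_mm <- sprintf("%.6f", out$x_mm)
  out$y_mm <- sprintf("%.6f", out$y_mm)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a morphometric feature table
#'
#' Reads a CSV of pre-computed features. Columns `subject_id` and `age` are
#' mandatory (chronological age is a model term); `true_stage` is optional;
#' any subset of the 24 parameter columns named as in [cvm_feature_names]
#' is accepted (a table holding only the features a given model needs is
#' valid for prediction-only use). Unknown columns are dropped with a
#' warning.
#'
#' @param path CSV file path.
#' @return A data frame of class `cvm_features`.
#' @export
read_feature_table <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("subject_id", "age")) {
    if (!col %in% names(raw)) {
      stop("feature table is missing mandatory column: ", col, call. = FALSE)
    }
  }
  known <- c("subject_id", "age", "true_stage", cvm_feature_names)
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warning("ignoring unknown feature column(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
    raw <- raw[, setdiff(names(raw), unknown), drop = FALSE]
  }
  raw$subject_id <- as.character(raw$subject_id)
  structure(raw, class = c("cvm_features", "data.frame"))
}

#' Write a morphometric feature table
#'
#' @param features A `cvm_features` data frame (from [extract_features()]
#'   or [read_feature_table()]).
#' @param path Output CSV path. Numeric columns are written with 6 decimals.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  out <- as.data.frame(features)
  num <- setdiff(names(out)[vapply(out, is.numeric, TRUE)], "true_stage")
  for (col in num) out[[col]] <- sprintf("%.6f", out[[col]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
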