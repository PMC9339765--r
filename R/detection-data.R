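#' Assemble a multi-surveyor detection dataset
#'
#' Bundles the tables that describe a multi-surveyor search of one or more
#' plots for sessile individuals (e.g. larval hibernacula): who searched
#' where and in what order, which individuals were found by whom, and the
#' individual/surveyor/plot metadata the estimators need.
#'
#' Each plot is searched by a sequence of surveyors ("occasions"); a
#' surveyor searches a given plot at most once. An individual belongs to
#' exactly one plot and its detection history is a 0/1 vector over that
#' plot's occasions. Occasions a surveyor did not search are simply absent
#' for that plot — a non-search is not a failed detection.
#'
#' @param individuals Data frame with columns `hibernaculum_id`, `plot_id`
#'   and optionally `species` (`"reducta"`, `"camilla"` or `"unknown"`),
#'   `occupancy` (`"full"`, `"empty"`, `"unknown"`) and `lost` (logical:
#'   disappeared during the study). Missing metadata columns are filled
#'   with `"unknown"`/`FALSE`.
#' @param surveyors Data frame with columns `surveyor_id` and `experience`
#'   (`"expert"` or `"novice"`).
#' @param occasions Data frame with columns `plot_id`, `occasion`
#'   (1-based search order within the plot) and `surveyor_id`.
#' @param detections Data frame in long form with columns `plot_id`,
#'   `hibernaculum_id`, `surveyor_id`, `detected` (0/1), one row per
#'   individual x occasion of its plot.
#' @param plots Optional data frame with columns `plot_id`, `area`
#'   (square metres, > 0) and optionally `host_plants` (count).
#'
#' @return An object of class `detection_data`: a list of validated
#'   tibbles `individuals`, `surveyors`, `occasions`, `detections`,
#'   `plots`.
#' @seealso [read_detections()], [simulate_population()], [plot_matrix()]
#' @export
detection_data <- function(individuals, surveyors, occasions, detections,
                           plots = NULL) {
  individuals <- tibble::as_tibble(individuals)
  surveyors <- tibble::as_tibble(surveyors)
  occasions <- tibble::as_tibble(occasions)
  detections <- tibble::as_tibble(detections)

  if (!"species" %in% names(individuals)) individuals$species <- "unknown"
  if (!"occupancy" %in% names(individuals)) individuals$occupancy <- "unknown"
  if (!"lost" %in% names(individuals)) individuals$lost <- FALSE
  individuals <- dplyr::select(
    individuals, "hibernaculum_id", "plot_id", "species", "occupancy", "lost"
  )
  individuals$lost <- as.logical(individuals$lost)

  if (is.null(plots)) {
    plots <- tibble::tibble(
      plot_id = unique(occasions$plot_id), area = NA_real_,
      host_plants = NA_integer_
    )
  } else {
    plots <- tibble::as_tibble(plots)
    if (!"host_plants" %in% names(plots)) plots$host_plants <- NA_integer_
    if (!"area" %in% names(plots)) plots$area <- NA_real_
    plots <- dplyr::select(plots, "plot_id", "area", "host_plants")
  }

  occasions <- dplyr::arrange(occasions, .data$plot_id, .data$occasion)

  ds <- structure(
    list(
      individuals = individuals, surveyors = surveyors,
      occasions = occasions, detections = detections, plots = plots
    ),
    class = "detection_data"
  )
  validate_detection_data(ds)
  ds
}

#' Validate a detection dataset
#'
#' Checks the structural invariants: binary detection entries, unique ids,
#' two-level experience, distinct surveyors per plot, positive areas, a
#' complete individual-by-occasion grid per plot, and (for field data,
#' where only detected individuals exist) at least one detection per
#' individual unless simulation ground truth is attached.
#'
#' @param ds A `detection_data` object.
#' @return `ds`, invisibly; errors describe the first violated invariant.
#' @export
validate_detection_data <- function(ds) {
  stopifnot(inherits(ds, "detection_data"))
  ind <- ds$individuals
  sv <- ds$surveyors
  occ <- ds$occasions
  det <- ds$detections

  if (anyDuplicated(sv$surveyor_id)) {
    stop("duplicate surveyor_id in surveyor table", call. = FALSE)
  }
  bad_exp <- setdiff(unique(sv$experience), c("expert", "novice"))
  if (length(bad_exp)) {
    stop("experience must be 'expert' or 'novice', found: ",
         paste(bad_exp, collapse = ", "), call. = FALSE)
  }
  dup <- ind |>
    dplyr::count(.data$plot_id, .data$hibernaculum_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop("duplicate hibernaculum_id within plot: ",
         paste(dup$hibernaculum_id, collapse = ", "), call. = FALSE)
  }
  bad_sp <- setdiff(unique(ind$species), c("reducta", "camilla", "unknown"))
  if (length(bad_sp)) {
    stop("unknown species label: ", paste(bad_sp, collapse = ", "),
         call. = FALSE)
  }
  bad_occ <- setdiff(unique(ind$occupancy), c("full", "empty", "unknown"))
  if (length(bad_occ)) {
    stop("unknown occupancy label: ", paste(bad_occ, collapse = ", "),
         call. = FALSE)
  }

  dup_occ <- occ |>
    dplyr::count(.data$plot_id, .data$surveyor_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup_occ)) {
    stop("surveyor searches a plot at most once; repeated: ",
         paste(dup_occ$surveyor_id, dup_occ$plot_id, collapse = "; "),
         call. = FALSE)
  }
  if (!all(occ$surveyor_id %in% sv$surveyor_id)) {
    miss <- setdiff(occ$surveyor_id, sv$surveyor_id)
    stop("occasion references unknown surveyor: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }

  if (!all(det$detected %in% c(0L, 1L))) {
    bad <- det[!det$detected %in% c(0L, 1L), ]
    stop("non-binary detection value '", bad$detected[1],
         "' for hibernaculum '", bad$hibernaculum_id[1], "', surveyor '",
         bad$surveyor_id[1], "'", call. = FALSE)
  }

  # grid completeness: every individual has exactly its plot's occasions
  key_exp <- ind |>
    dplyr::inner_join(occ, by = "plot_id", relationship = "many-to-many") |>
    dplyr::select("plot_id", "hibernaculum_id", "surveyor_id")
  key_obs <- dplyr::select(det, "plot_id", "hibernaculum_id", "surveyor_id")
  if (nrow(dplyr::anti_join(
    key_exp, key_obs,
    by = c("plot_id", "hibernaculum_id", "surveyor_id")
  )) ||
    nrow(dplyr::anti_join(
      key_obs, key_exp,
      by = c("plot_id", "hibernaculum_id", "surveyor_id")
    ))) {
    stop("detections do not form a complete individual-by-occasion grid ",
         "for each plot", call. = FALSE)
  }

  if (any(!is.na(ds$plots$area) & ds$plots$area <= 0)) {
    stop("plot area must be strictly positive", call. = FALSE)
  }

  if (is.null(attr(ds, "ground_truth")) && nrow(ind)) {
    ndet <- det |>
      dplyr::summarise(
        n = sum(.data$detected),
        .by = c("plot_id", "hibernaculum_id")
      )
    if (any(ndet$n == 0)) {
      stop("field data must not contain never-detected individuals ",
           "(first offender: ",
           ndet$hibernaculum_id[which(ndet$n == 0)[1]], ")", call. = FALSE)
    }
  }
  invisible(ds)
}

#' @export
print.detection_data <- function(x, ...) {
  npl <- nrow(x$plots)
  cat("<detection_data> ", nrow(x$individuals), " individuals, ",
      nrow(x$surveyors), " surveyors, ", npl,
      if (npl == 1) " plot\n" else " plots\n", sep = "")
  per <- x$occasions |>
    dplyr::summarise(occasions = dplyr::n(), .by = "plot_id") |>
    dplyr::left_join(
      dplyr::count(x$individuals, .data$plot_id, name = "individuals"),
      by = "plot_id"
    )
  print(per, n = Inf)
  if (!is.null(attr(x, "ground_truth"))) {
    cat("ground truth attached (synthetic dataset)\n")
  }
  invisible(x)
}

#' Extract one plot's detection matrix
#'
#' @param ds A `detection_data` object.
#' @param plot Plot id.
#' @return Binary matrix, individuals x occasions; columns named by
#'   surveyor in search order, rows by hibernaculum id.
#' @export
plot_matrix <- function(ds, plot) {
  occ <- occasions_of(ds, plot)
  ind <- dplyr::filter(ds$individuals, .data$plot_id == plot)
  det <- dplyr::filter(ds$detections, .data$plot_id == plot)
  m <- matrix(0L, nrow(ind), nrow(occ),
              dimnames = list(ind$hibernaculum_id, occ$surveyor_id))
  if (nrow(det)) {
    m[cbind(
      match(det$hibernaculum_id, ind$hibernaculum_id),
      match(det$surveyor_id, occ$surveyor_id)
    )] <- as.integer(det$detected)
  }
  m
}

occasions_of <- function(ds, plot) {
  if (!plot %in% ds$occasions$plot_id) {
    stop("unknown plot id: ", plot, call. = FALSE)
  }
  ds$occasions |>
    dplyr::filter(.data$plot_id == plot) |>
    dplyr::arrange(.data$occasion)
}

#' Remove individuals that disappeared during the study
#'
#' Demographic closure requires that no individuals enter or leave the
#' population between occasions. Individuals flagged `lost` (the shelter
#' disappeared mid-study) violate closure and are dropped before
#' estimation; the count removed is recorded in the `n_removed` attribute.
#' Idempotent.
#'
#' @param ds A `detection_data` object.
#' @return A `detection_data` object without lost individuals; attribute
#'   `n_removed` gives the number dropped.
#' @export
filter_closure <- function(ds) {
  lost <- ds$individuals |>
    dplyr::filter(.data$lost)
  keep <- dplyr::filter(ds$individuals, !.data$lost)
  out <- ds
  out$individuals <- keep
  out$detections <- dplyr::semi_join(
    ds$detections, keep,
    by = c("plot_id", "hibernaculum_id")
  )
  attr(out, "ground_truth") <- attr(ds, "ground_truth")
  attr(out, "n_removed") <- nrow(lost)
  validate_detection_data(out)
  out
}

#' Minimum larva number (MLN)
#'
#' The number of distinct individuals detected at least once — a direct
#' lower bound on abundance requiring no model.
#'
#' @param ds A `detection_data` object.
#' @param plot Optional plot id; default all plots.
#' @return A tibble with columns `plot_id`, `mln`.
#' @export
mln <- function(ds, plot = NULL) {
  if (!is.null(plot) && !plot %in% ds$plots$plot_id) {
    stop("unknown plot id: ", plot, call. = FALSE)
  }
  out <- ds$detections |>
    dplyr::summarise(
      any_det = any(.data$detected == 1),
      .by = c("plot_id", "hibernaculum_id")
    ) |>
    dplyr::summarise(mln = sum(.data$any_det), .by = "plot_id")
  out <- ds$plots |>
    dplyr::select("plot_id") |>
    dplyr::left_join(out, by = "plot_id") |>
    dplyr::mutate(mln = dplyr::coalesce(.data$mln, 0L))
  if (!is.null(plot)) out <- dplyr::filter(out, .data$plot_id == plot)
  out
}

#' Fraction of empty hibernacula among labelled individuals
#'
#' Empty shelters at the end of winter approximate overwinter mortality:
#' the larva was predated or died but the shelter remained findable.
#'
#' @param ds A `detection_data` object.
#' @param by_plot Also return per-plot fractions?
#' @return A tibble with `n_full`, `n_empty`, `empty_fraction` (overall
#'   row has `plot_id = "all"`), restricted to individuals whose
#'   occupancy was recorded.
#' @export
empty_fraction <- function(ds, by_plot = FALSE) {
  lab <- dplyr::filter(ds$individuals, .data$occupancy != "unknown")
  if (!nrow(lab)) stop("no individuals with occupancy labels", call. = FALSE)
  tally <- function(d, id) {
    tibble::tibble(
      plot_id = id,
      n_full = sum(d$occupancy == "full"),
      n_empty = sum(d$occupancy == "empty")
    )
  }
  out <- tally(lab, "all")
  if (by_plot) {
    out <- dplyr::bind_rows(
      lab |>
        dplyr::group_split(.data$plot_id) |>
        purrr::map(\(d) tally(d, d$plot_id[1])) |>
        dplyr::bind_rows(),
      out
    )
  }
  dplyr::mutate(
    out,
    empty_fraction = .data$n_empty / (.data$n_full + .data$n_empty)
  )
}
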