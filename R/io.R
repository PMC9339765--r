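META_COLS <- c("hibernaculum_id", "plot_id", "species", "occupancy", "lost")

#' Read a detection dataset from CSV
#'
#' Expects the wide layout: one row per individual, the metadata columns
#' `hibernaculum_id, plot_id, species, occupancy, lost`, then one 0/1
#' column per surveyor in search order. An empty cell means that surveyor
#' did not search that individual's plot (structurally different from a
#' missed detection, which is 0). A companion surveyors CSV maps
#' `surveyor_id` to `experience`.
#'
#' Deposited field tables use varying headers; `col_map` renames them,
#' e.g. `col_map = c(hibernaculum_id = "ID", plot_id = "Plot")`.
#'
#' @param path Detections CSV.
#' @param surveyors_path Surveyors CSV (`surveyor_id, experience`).
#' @param plots_path Optional plots CSV (`plot_id, area, host_plants`).
#' @param col_map Optional named character vector mapping canonical
#'   metadata names to the file's column names.
#' @return A validated [detection_data()] object.
#' @export
read_detections <- function(path, surveyors_path, plots_path = NULL,
                            col_map = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      names(raw)[names(raw) == col_map[[canon]]] <- canon
    }
  }
  need <- c("hibernaculum_id", "plot_id")
  if (!all(need %in% names(raw))) {
    stop("detections CSV must contain columns ",
         paste(setdiff(need, names(raw)), collapse = ", "),
         " (use col_map to rename)", call. = FALSE)
  }
  for (m in setdiff(META_COLS, names(raw))) {
    raw[[m]] <- if (m == "lost") "FALSE" else "unknown"
  }
  sv_cols <- setdiff(names(raw), META_COLS)
  if (!length(sv_cols)) stop("no surveyor columns found", call. = FALSE)

  for (cc in sv_cols) {
    bad <- !is.na(raw[[cc]]) & !raw[[cc]] %in% c("0", "1")
    if (any(bad)) {
      i <- which(bad)[1]
      stop("non-binary value '", raw[[cc]][i], "' in column '", cc,
           "', row ", i, " (hibernaculum '", raw$hibernaculum_id[i], "')",
           call. = FALSE)
    }
  }

  surveyors <- readr::read_csv(
    surveyors_path,
    col_types = readr::cols(.default = "c"), progress = FALSE
  )
  if (!all(c("surveyor_id", "experience") %in% names(surveyors))) {
    stop("surveyors CSV must contain surveyor_id and experience",
         call. = FALSE)
  }
  unknown_cols <- setdiff(sv_cols, surveyors$surveyor_id)
  if (length(unknown_cols)) {
    stop("detection columns name surveyors absent from the surveyor ",
         "table: ", paste(unknown_cols, collapse = ", "), call. = FALSE)
  }

  plots <- NULL
  if (!is.null(plots_path)) {
    plots <- readr::read_csv(
      plots_path,
      col_types = readr::cols(
        plot_id = "c", .default = readr::col_double()
      ),
      progress = FALSE
    )
  }

  individuals <- raw |>
    dplyr::select(dplyr::all_of(META_COLS)) |>
    dplyr::mutate(lost = toupper(.data$lost) %in% c("TRUE", "T", "1"))

  # per plot, occasion order = CSV column order among searched columns;
  # a column is "searched" for a plot iff its cells are non-missing there
  long <- raw |>
    dplyr::select(
      "hibernaculum_id", "plot_id", dplyr::all_of(sv_cols)
    ) |>
    tidyr::pivot_longer(
      dplyr::all_of(sv_cols),
      names_to = "surveyor_id", values_to = "detected"
    )
  searched <- long |>
    dplyr::summarise(
      n_na = sum(is.na(.data$detected)), n = dplyr::n(),
      .by = c("plot_id", "surveyor_id")
    )
  mixed <- dplyr::filter(searched, .data$n_na > 0, .data$n_na < .data$n)
  if (nrow(mixed)) {
    stop("column '", mixed$surveyor_id[1], "' is partially missing in ",
         "plot '", mixed$plot_id[1],
         "': a surveyor either searched a plot (all 0/1) or did not ",
         "(all empty)", call. = FALSE)
  }
  occasions <- searched |>
    dplyr::filter(.data$n_na == 0) |>
    dplyr::mutate(
      occasion = match(.data$surveyor_id, sv_cols),
      .by = "plot_id"
    ) |>
    dplyr::arrange(.data$plot_id, .data$occasion) |>
    dplyr::mutate(occasion = seq_len(dplyr::n()), .by = "plot_id") |>
    dplyr::select("plot_id", "occasion", "surveyor_id")

  detections <- long |>
    dplyr::filter(!is.na(.data$detected)) |>
    dplyr::mutate(detected = as.integer(.data$detected))

  detection_data(individuals, surveyors, occasions, detections, plots)
}

# global column order consistent with every plot's search order
# (Kahn topological sort over consecutive-pair precedence)
global_surveyor_order <- function(ds) {
  ids <- unique(ds$occasions$surveyor_id)
  edges <- ds$occasions |>
    dplyr::group_split(.data$plot_id) |>
    purrr::map(\(d) {
      s <- d$surveyor_id[order(d$occasion)]
      if (length(s) < 2) return(NULL)
      tibble::tibble(from = s[-length(s)], to = s[-1])
    }) |>
    dplyr::bind_rows() |>
    dplyr::distinct()
  order_out <- character(0)
  indeg <- stats::setNames(
    purrr::map_int(ids, \(i) sum(edges$to == i)), ids
  )
  avail <- ids[indeg[ids] == 0]
  while (length(avail)) {
    v <- avail[1]
    avail <- avail[-1]
    order_out <- c(order_out, v)
    outs <- edges$to[edges$from == v]
    edges <- edges[edges$from != v, , drop = FALSE]
    for (w in outs) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L && sum(edges$to == w) == 0L) {
        avail <- c(avail, w)
      }
    }
  }
  if (length(order_out) < length(ids)) {
    stop("per-plot search orders are mutually inconsistent; no single ",
         "column order can represent them", call. = FALSE)
  }
  order_out
}

#' Write a detection dataset to CSV
#'
#' Inverse of [read_detections()]; the surveyor column order is a global
#' order consistent with every plot's search order.
#'
#' @param ds A `detection_data` object.
#' @param path Detections CSV path.
#' @param surveyors_path Optional surveyors CSV path.
#' @param plots_path Optional plots CSV path.
#' @return `ds`, invisibly.
#' @export
write_detections <- function(ds, path, surveyors_path = NULL,
                             plots_path = NULL) {
  ord <- global_surveyor_order(ds)
  wide <- ds$detections |>
    tidyr::pivot_wider(
      id_cols = c("plot_id", "hibernaculum_id"),
      names_from = "surveyor_id", values_from = "detected"
    )
  for (s in setdiff(ord, names(wide))) wide[[s]] <- NA_integer_
  out <- ds$individuals |>
    dplyr::left_join(wide, by = c("plot_id", "hibernaculum_id")) |>
    dplyr::select(dplyr::all_of(c(META_COLS, ord)))
  readr::write_csv(out, path, na = "")
  if (!is.null(surveyors_path)) {
    readr::write_csv(ds$surveyors, surveyors_path)
  }
  if (!is.null(plots_path)) readr::write_csv(ds$plots, plots_path)
  invisible(ds)
}

#' Write MARK-style encounter histories (.inp)
#'
#' One line per individual: an id comment, the encounter-history string
#' over the global occasion (surveyor) order, then one frequency column
#' per plot (the group). Occasions a surveyor did not search in the
#' individual's plot are written as `.` (not available), the MARK
#' convention for structurally missing occasions.
#'
#' @param ds A `detection_data` object.
#' @param path Output path.
#' @return `ds`, invisibly.
#' @export
write_inp <- function(ds, path) {
  ord <- global_surveyor_order(ds)
  plot_ids <- ds$plots$plot_id
  lines <- c(
    paste0("/* occasions: ", paste(ord, collapse = " "), " */"),
    paste0("/* groups: ", paste(plot_ids, collapse = " "), " */")
  )
  for (p in plot_ids) {
    m <- plot_matrix(ds, p)
    hist_chr <- apply(m, 1, function(row) {
      full <- rep(".", length(ord))
      full[match(colnames(m), ord)] <- as.character(row)
      paste(full, collapse = "")
    })
    freq <- paste(ifelse(plot_ids == p, "1", "0"), collapse = " ")
    if (nrow(m)) {
      lines <- c(lines, paste0(
        "/* ", rownames(m), " */ ", hist_chr, " ", freq, ";"
      ))
    }
  }
  writeLines(lines, path)
  invisible(ds)
}

#' Read MARK-style encounter histories (.inp)
#'
#' Parses files written by [write_inp()] (occasion and group metadata are
#' taken from the two header comments). Individual metadata beyond plot
#' membership is not carried by the format and comes back as `unknown`.
#'
#' @param path Input path.
#' @param surveyors Surveyor table (`surveyor_id, experience`); defaults
#'   to all-`novice` if omitted.
#' @return A [detection_data()] object.
#' @export
read_inp <- function(path, surveyors = NULL) {
  lines <- readLines(path)
  occ_line <- grep("^/\\* occasions:", lines, value = TRUE)
  grp_line <- grep("^/\\* groups:", lines, value = TRUE)
  if (!length(occ_line) || !length(grp_line)) {
    stop(".inp file lacks the occasions/groups header comments",
         call. = FALSE)
  }
  ord <- strsplit(sub("^/\\* occasions: (.*) \\*/$", "\\1", occ_line[1]),
                  " ")[[1]]
  plot_ids <- strsplit(sub("^/\\* groups: (.*) \\*/$", "\\1", grp_line[1]),
                       " ")[[1]]
  rec <- grep(";\\s*$", lines, value = TRUE)
  parsed <- stringr::str_match(
    rec, "^(?:/\\* (\\S+) \\*/ )?([01.]+)\\s+([01 ]+);\\s*$"
  )
  if (any(is.na(parsed[, 3]))) {
    stop("malformed encounter-history line: ",
         rec[which(is.na(parsed[, 3]))[1]], call. = FALSE)
  }
  ids <- parsed[, 2]
  ids[is.na(ids)] <- paste0("ind_", seq_len(sum(is.na(ids))))
  hist <- parsed[, 3]
  freq <- parsed[, 4]
  plot_of <- purrr::map_chr(strsplit(trimws(freq), "\\s+"), \(f) {
    plot_ids[which(f == "1")[1]]
  })
  rows <- purrr::pmap(
    list(ids, hist, plot_of),
    function(id, h, p) {
      ch <- strsplit(h, "")[[1]]
      keep <- ch != "."
      tibble::tibble(
        plot_id = p, hibernaculum_id = id,
        surveyor_id = ord[keep], detected = as.integer(ch[keep]),
        pos = which(keep)
      )
    }
  ) |> dplyr::bind_rows()
  occasions <- rows |>
    dplyr::distinct(.data$plot_id, .data$surveyor_id, .data$pos) |>
    dplyr::arrange(.data$plot_id, .data$pos) |>
    dplyr::mutate(occasion = seq_len(dplyr::n()), .by = "plot_id") |>
    dplyr::select("plot_id", "occasion", "surveyor_id")
  individuals <- rows |>
    dplyr::distinct(.data$plot_id, .data$hibernaculum_id)
  if (is.null(surveyors)) {
    surveyors <- tibble::tibble(
      surveyor_id = ord, experience = "novice"
    )
  }
  detection_data(
    individuals, surveyors, occasions,
    dplyr::select(rows, -"pos"),
    tibble::tibble(plot_id = plot_ids)
  )
}
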