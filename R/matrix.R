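# Prediction of which GMOs an element-specific detection method can
# identify, from element annotations and the hierarchy alone. A method
# whose assay targets an element also detects GMOs annotated with narrower
# variants of that element (they contain its sequence); a GMO annotated
# only with a broader term than a variant-specific target may or may not
# carry the variant, so the call is "possible" rather than a hard yes or
# no.

DETECTION_CALLS <- c("detected", "possible", "not_detected")

check_annotations <- function(th, gmos, methods) {
  gmos <- tibble::as_tibble(gmos)
  methods <- tibble::as_tibble(methods)
  stopifnot(
    all(c("gmo_id", "element_id") %in% names(gmos)),
    all(c("method_id", "target_id") %in% names(methods))
  )
  gmos$element_id <- ifelse(
    is.na(gmos$element_id) | !nzchar(gmos$element_id),
    NA_character_, normalize_eid(gmos$element_id)
  )
  methods$target_id <- normalize_eid(methods$target_id)
  known <- th$terms$term_id
  bad_el <- setdiff(gmos$element_id[!is.na(gmos$element_id)], known)
  if (length(bad_el)) {
    rlang::abort(paste0(
      "unknown element id in GMO annotations: ",
      paste(bad_el, collapse = ", ")
    ))
  }
  lev <- stats::setNames(th$terms$level, known)
  shallow <- gmos$element_id[!is.na(gmos$element_id) &
                               lev[gmos$element_id] < 3L]
  if (length(shallow)) {
    rlang::abort(paste0(
      "GMO annotations must use level 3-4 terms: ",
      paste(unique(shallow), collapse = ", ")
    ))
  }
  bad_t <- setdiff(methods$target_id, known)
  if (length(bad_t)) {
    rlang::abort(paste0(
      "unknown method target: ", paste(bad_t, collapse = ", ")
    ))
  }
  list(gmos = gmos, methods = methods)
}

#' Predict GMO detectability per element-specific method
#'
#' For every GMO x method pair the call is: `detected` if some annotated
#' element lies in the reflexive-transitive closure of the method's target
#' (the GMO carries the target element or a narrower variant of it);
#' `possible` if no such element exists but some annotated element is a
#' strict ancestor of the target (the annotation is broader than the
#' variant-specific assay, so presence of the target sequence is
#' unconfirmed); `not_detected` otherwise.
#'
#' @param th a `gmo_thesaurus`.
#' @param gmos tibble of GMO annotations with columns `gmo_id`,
#'   `element_id` (one row per annotation; a row with `NA` element
#'   declares a GMO with no annotations). Elements must be level 3-4
#'   terms.
#' @param methods tibble with columns `method_id`, `target_id` (level 2-4
#'   thesaurus terms).
#' @param binary collapse `possible` to `not_detected` for consumers that
#'   need a two-valued matrix.
#' @return A tibble of class `gmo_detection_matrix` with columns `gmo_id`,
#'   `method_id`, `call`; every pair appears exactly once, ordered by GMO
#'   then method.
#' @export
#' @examples
#' th <- build_example_thesaurus()
#' gmos <- tibble::tibble(gmo_id = "MON-00810-6",
#'                        element_id = "e:0000300")
#' methods <- tibble::tibble(method_id = "qPCR-cry1Ab",
#'                           target_id = "e:0000203")
#' predict_detection(th, gmos, methods)
predict_detection <- function(th, gmos, methods, binary = FALSE) {
  ann <- check_annotations(th, gmos, methods)
  gmos <- ann$gmos
  methods <- ann$methods
  gmo_ids <- unique(gmos$gmo_id)
  method_tbl <- dplyr::distinct(methods, .data$method_id, .data$target_id)
  if (anyDuplicated(method_tbl$method_id)) {
    rlang::abort("a method_id maps to more than one target")
  }
  elements_of <- lapply(
    split(gmos$element_id, factor(gmos$gmo_id, levels = gmo_ids)),
    function(x) unique(x[!is.na(x)])
  )
  closure_of <- lapply(
    stats::setNames(method_tbl$target_id, method_tbl$method_id),
    function(tid) expand_term(th, tid)
  )
  ancestors_of <- lapply(
    stats::setNames(method_tbl$target_id, method_tbl$method_id),
    function(tid) ancestors(th, tid)
  )
  grid <- tidyr::expand_grid(
    gmo_id = gmo_ids, method_id = method_tbl$method_id
  )
  grid$call <- purrr::map2_chr(grid$gmo_id, grid$method_id, function(g, m) {
    els <- elements_of[[g]]
    if (any(els %in% closure_of[[m]])) {
      "detected"
    } else if (any(els %in% ancestors_of[[m]])) {
      "possible"
    } else {
      "not_detected"
    }
  })
  if (binary) {
    grid$call[grid$call == "possible"] <- "not_detected"
  }
  grid$call <- factor(grid$call, levels = DETECTION_CALLS)
  grid <- dplyr::arrange(grid, .data$gmo_id, .data$method_id)
  class(grid) <- c("gmo_detection_matrix", class(grid))
  grid
}

#' Summarize a detection matrix
#'
#' @param matrix a `gmo_detection_matrix` from [predict_detection()].
#' @return A list of class `gmo_detection_coverage` with two tibbles:
#'   `methods` (per method: counts of detected / possible / not_detected
#'   GMOs) and `gmos` (per GMO: the methods that detect it, `|`-joined).
#'   Both deterministically ordered.
#' @export
coverage_report <- function(matrix) {
  stopifnot(all(c("gmo_id", "method_id", "call") %in% names(matrix)))
  m <- tibble::as_tibble(matrix)
  if (nrow(m) == 0L) {
    return(structure(
      list(
        methods = tibble::tibble(
          method_id = character(), detected = integer(),
          possible = integer(), not_detected = integer()
        ),
        gmos = tibble::tibble(
          gmo_id = character(), n_detected = integer(),
          detecting_methods = character()
        )
      ),
      class = "gmo_detection_coverage"
    ))
  }
  methods <- m |>
    dplyr::count(.data$method_id, .data$call, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "call", values_from = "n",
                       values_fill = 0L) |>
    dplyr::arrange(.data$method_id)
  for (col in DETECTION_CALLS) {
    if (!col %in% names(methods)) methods[[col]] <- 0L
  }
  methods <- methods[, c("method_id", DETECTION_CALLS)]
  gmos <- m |>
    dplyr::group_by(.data$gmo_id) |>
    dplyr::summarise(
      n_detected = sum(.data$call == "detected"),
      detecting_methods = paste(
        sort(.data$method_id[.data$call == "detected"]), collapse = "|"
      ),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$gmo_id)
  structure(list(methods = methods, gmos = gmos),
            class = "gmo_detection_coverage")
}

#' @export
print.gmo_detection_coverage <- function(x, ...) {
  cat("<gmo_detection_coverage>\n")
  cat("per-method calls:\n")
  print(x$methods, ...)
  cat("per-GMO detecting methods:\n")
  print(x$gmos, ...)
  invisible(x)
}

#' Reshape a detection matrix to the wide GMO x method grid
#'
#' @param matrix a `gmo_detection_matrix`.
#' @param file optional path; when given the grid is written as TSV with a
#'   header row of method ids and cells D/P/N.
#' @return A tibble, one row per GMO, one column per method.
#' @export
detection_wide <- function(matrix, file = NULL) {
  m <- tibble::as_tibble(matrix)
  m$cell <- unname(c(detected = "D", possible = "P", not_detected = "N")[
    as.character(m$call)
  ])
  wide <- tidyr::pivot_wider(
    m[, c("gmo_id", "method_id", "cell")],
    names_from = "method_id", values_from = "cell"
  )
  wide <- dplyr::arrange(wide, .data$gmo_id)
  if (!is.null(file)) {
    utils::write.table(wide, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  wide
}

#' Read GMO annotation / method assignment tables
#'
#' Plain TSV, no header: `gmo_id<TAB>element_id` one annotation per line
#' (an empty second field declares a GMO without annotations), and
#' `method_id<TAB>target_id` one method per line.
#'
#' @param path file path.
#' @return A tibble with the respective two columns.
#' @export
read_gmo_annotations <- function(path) {
  df <- utils::read.table(
    path, sep = "\t", header = FALSE, quote = "", comment.char = "#",
    col.names = c("gmo_id", "element_id"), colClasses = "character",
    fill = TRUE, encoding = "UTF-8"
  )
  out <- tibble::as_tibble(df)
  out$element_id[!nzchar(out$element_id)] <- NA_character_
  out
}

#' @rdname read_gmo_annotations
#' @export
read_method_specs <- function(path) {
  df <- utils::read.table(
    path, sep = "\t", header = FALSE, quote = "", comment.char = "#",
    col.names = c("method_id", "target_id"), colClasses = "character",
    encoding = "UTF-8"
  )
  tibble::as_tibble(df)
}

#' Plot a detection matrix as a GMO x method tile grid
#'
#' @param object a `gmo_detection_matrix`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gmo_detection_matrix <- function(object, ...) {
  m <- tibble::as_tibble(object)
  ggplot2::ggplot(m, ggplot2::aes(
    x = .data$method_id, y = .data$gmo_id, fill = .data$call
  )) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_manual(
      values = c(detected = "#1b7837", possible = "#fdb863",
                 not_detected = "grey85"),
      drop = FALSE
    ) +
    ggplot2::labs(x = "method", y = "GMO", fill = "call") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
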