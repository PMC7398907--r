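#' Define a growth medium
#'
#' A medium is a table mapping exchange-reaction ids to maximal uptake rates
#' (non-negative magnitudes, model units). Uptake through an exchange written
#' as `met_e ->` is a negative flux, so applying a medium sets the exchange's
#' lower bound to `-uptake`; secretion (the positive direction) is left open.
#'
#' @param uptakes A named numeric vector or a data frame with columns
#'   `exchange` and `uptake`.
#' @param name Optional medium name.
#' @return A tibble of class `pa_media` with columns `exchange`, `uptake`.
#' @examples
#' media(c(EX_glc = 10, EX_nh4 = 10), name = "glucose-ammonium")
#' @export
media <- function(uptakes = NULL, name = "medium") {
  tbl <- if (is.null(uptakes)) {
    tibble(exchange = character(0), uptake = numeric(0))
  } else if (is.data.frame(uptakes)) {
    as_tibble(uptakes)[, c("exchange", "uptake")]
  } else {
    tibble(exchange = names(uptakes), uptake = unname(uptakes))
  }
  if (any(is.na(tbl$uptake)) || any(tbl$uptake < 0)) {
    abort("Media uptake values must be non-negative.")
  }
  if (anyDuplicated(tbl$exchange)) {
    abort("Duplicate exchange ids in media.")
  }
  structure(tbl, class = c("pa_media", class(tibble())), media_name = name)
}

#' @export
as_media <- function(x, ...) UseMethod("as_media")

#' @export
as_media.pa_media <- function(x, ...) x

#' @export
as_media.default <- function(x, ...) media(x, ...)

#' Merge supplements into a medium
#'
#' Later entries win: a supplement overriding an existing exchange keeps the
#' supplement's bound.
#'
#' @param base A `pa_media`.
#' @param supplements Named numeric vector or `pa_media` of additions.
#' @return A `pa_media`.
#' @export
media_with <- function(base, supplements) {
  base <- as_media(base)
  sup <- as_media(supplements)
  keep <- base[!base$exchange %in% sup$exchange, ]
  media(bind_rows(keep, as_tibble(sup)),
        name = attr(base, "media_name") %||% "medium")
}

#' Constrain a model to a medium
#'
#' Every exchange reaction absent from the medium has its uptake closed
#' (lower bound 0); listed exchanges get lower bound `-uptake`. Secretion
#' bounds are untouched. Non-exchange reactions are untouched. The input
#' model is not modified. Media ids that name a non-exchange reaction are an
#' error; ids absent from the model are ignored, so a generic mineral medium
#' can be applied to a fixture that lacks some ion exchanges.
#'
#' @param model A `metabolic_model`.
#' @param media A `pa_media` or named numeric vector of uptake bounds.
#' @return A new `metabolic_model`.
#' @examples
#' m <- apply_media(make_toy_model("TOY-1"), c(EX_glc = 10, EX_nh4 = 10))
#' @export
apply_media <- function(model, media) {
  media <- as_media(media)
  present <- media$exchange %in% model$reactions$id
  if (any(present)) {
    rt <- model$reactions$rtype[match(media$exchange[present],
                                      model$reactions$id)]
    if (any(rt != "exchange")) {
      abort(sprintf("Media id(s) not exchange reactions: %s.",
                    paste(media$exchange[present][rt != "exchange"],
                          collapse = ", ")))
    }
  }
  rxns <- model$reactions
  is_ex <- rxns$rtype == "exchange"
  rxns$lower_bound[is_ex] <- 0
  idx <- match(media$exchange[present], rxns$id)
  rxns$lower_bound[idx] <- -media$uptake[present]
  out <- model
  out$reactions <- rxns
  out
}

#' Read / write media tables
#'
#' Tab-delimited with header columns `exchange` and `uptake`.
#'
#' @param path File path.
#' @return `read_media` returns a `pa_media`.
#' @export
read_media <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("exchange", "uptake") %in% names(tbl))) {
    abort("Media table needs columns `exchange` and `uptake`.")
  }
  media(tbl, name = basename(path))
}

#' @rdname read_media
#' @param media A `pa_media`.
#' @export
write_media <- function(media, path) {
  readr::write_tsv(as_tibble(as_media(media)), path)
  invisible(path)
}
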