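#' @importFrom tibble tibble as_tibble
NULL

BEHAVIOR_KINDS <- c("chunk_scored", "whole_video")
VALUE_DOMAINS <- c("binary", "seconds", "ordinal_0_4")

#' Construct an ethogram
#'
#' An ethogram is the catalogue of behaviors scored in an assay. Each
#' behavior is either `chunk_scored` (rated present/absent in each short
#' randomized chunk, so its value domain is always `binary`) or
#' `whole_video` (a single measure per recording, e.g. a latency in
#' seconds or an ordinal nest score).
#'
#' @param behaviors a data frame with columns `name`, `kind`,
#'   `value_domain`, `description` (the last two optional; defaults are
#'   filled from `kind`).
#' @return an object of class `ethogram`: a tibble with one row per
#'   behavior, in the declared order.
#' @export
#' @examples
#' eth <- ethogram(data.frame(
#'   name = c("grooming", "latency to emerge"),
#'   kind = c("chunk_scored", "whole_video")
#' ))
#' nrow(eth)
ethogram <- function(behaviors) {
  behaviors <- as_tibble(as.data.frame(behaviors, stringsAsFactors = FALSE))
  if (nrow(behaviors) == 0L) {
    stop("ethogram must define at least one behavior", call. = FALSE)
  }
  if (!all(c("name", "kind") %in% names(behaviors))) {
    stop("behaviors must have columns 'name' and 'kind'", call. = FALSE)
  }
  behaviors$name <- as.character(behaviors$name)
  behaviors$kind <- as.character(behaviors$kind)
  if (any(!nzchar(behaviors$name)) || anyNA(behaviors$name)) {
    stop("behavior names must be non-empty", call. = FALSE)
  }
  dup <- unique(behaviors$name[duplicated(behaviors$name)])
  if (length(dup) > 0L) {
    stop("duplicate behavior name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_kind <- setdiff(unique(behaviors$kind), BEHAVIOR_KINDS)
  if (length(bad_kind) > 0L) {
    stop("unknown behavior kind(s): ", paste(bad_kind, collapse = ", "),
         "; expected one of: ", paste(BEHAVIOR_KINDS, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(behaviors$value_domain)) {
    behaviors$value_domain <- ifelse(behaviors$kind == "chunk_scored",
                                     "binary", "seconds")
  }
  behaviors$value_domain <- as.character(behaviors$value_domain)
  bad_dom <- setdiff(unique(behaviors$value_domain), VALUE_DOMAINS)
  if (length(bad_dom) > 0L) {
    stop("unknown value_domain(s): ", paste(bad_dom, collapse = ", "),
         call. = FALSE)
  }
  # chunk-scored behaviors are present/absent by construction
  cs_bad <- behaviors$kind == "chunk_scored" & behaviors$value_domain != "binary"
  if (any(cs_bad)) {
    stop("chunk_scored behaviors must have binary value_domain: ",
         paste(behaviors$name[cs_bad], collapse = ", "), call. = FALSE)
  }
  if (is.null(behaviors$description)) behaviors$description <- ""
  behaviors$description <- as.character(behaviors$description)
  out <- behaviors[, c("name", "kind", "value_domain", "description")]
  class(out) <- c("ethogram", class(out))
  out
}

#' Default maternal-behavior ethogram
#'
#' The stock ethogram for the dam maternal behavior test: nine behaviors
#' scored present/absent per chunk, plus three whole-video parameters
#' (latency to initiate pup retrieval, latency to complete retrieval,
#' and the ordinal 0-4 nest score at assay end).
#'
#' @return an [ethogram()] with 12 behaviors (9 chunk-scored, 3 whole-video).
#' @export
#' @examples
#' eth <- default_ethogram()
#' table(eth$kind)
default_ethogram <- function() {
  ethogram(tibble(
    name = c(
      "all pups retrieved and grouped",
      "all pups nested",
      "pup retrieval",
      "pup interaction",
      "crouching over pups",
      "resting with pups",
      "nest building",
      "solo activity",
      "solo rest",
      "latency to initiate retrieval",
      "latency to complete retrieval",
      "nest score"
    ),
    kind = c(rep("chunk_scored", 9L), rep("whole_video", 3L)),
    value_domain = c(rep("binary", 9L), "seconds", "seconds", "ordinal_0_4"),
    description = c(
      "every pup has been carried back and lies grouped in the nest",
      "every pup is inside the nest",
      "dam carries a displaced pup back toward the nest",
      "sniffing or anogenital licking of pups",
      "dam crouches in nursing posture over pups",
      "dam rests in contact with pups",
      "dam manipulates nesting material",
      "locomotion/exploration away from pups",
      "resting away from pups",
      "seconds from assay start to first retrieval, censored at cutoff",
      "seconds from assay start to last pup grouped, censored at assay end",
      "ordinal nest quality at assay end: 0 none .. 4 high structured walls"
    )
  ))
}

#' Chunk-scored behavior names of an ethogram
#' @param eth an [ethogram()].
#' @return character vector in declared order.
#' @export
chunk_behaviors <- function(eth) {
  stopifnot(inherits(eth, "ethogram"))
  eth$name[eth$kind == "chunk_scored"]
}

#' Load an ethogram from a JSON or YAML config file
#'
#' The config is a list of records with fields `name`, `kind` and
#' optionally `value_domain` and `description`. With `source = NULL` the
#' default maternal-behavior ethogram is returned.
#'
#' @param source path to a `.json`/`.yaml`/`.yml` file, or `NULL` for the
#'   default fixture.
#' @param format `"auto"` (by file extension), `"json"`, or `"yaml"`.
#' @return an [ethogram()].
#' @export
load_ethogram <- function(source = NULL, format = c("auto", "json", "yaml")) {
  format <- match.arg(format)
  if (is.null(source)) return(default_ethogram())
  if (format == "auto") {
    format <- if (grepl("\\.ya?ml$", source, ignore.case = TRUE)) "yaml" else "json"
  }
  records <- if (format == "yaml") {
    yaml::read_yaml(source)
  } else {
    jsonlite::fromJSON(source, simplifyDataFrame = FALSE)
  }
  if (length(records) == 0L) {
    stop("ethogram config defines zero behaviors: ", source, call. = FALSE)
  }
  rows <- lapply(records, function(r) {
    if (is.null(r$name) || is.null(r$kind)) {
      stop("each behavior needs 'name' and 'kind' fields", call. = FALSE)
    }
    tibble(
      name = as.character(r$name),
      kind = as.character(r$kind),
      value_domain = as.character(
        if (is.null(r$value_domain)) {
          if (identical(r$kind, "chunk_scored")) "binary" else "seconds"
        } else r$value_domain
      ),
      description = as.character(if (is.null(r$description)) "" else r$description)
    )
  })
  ethogram(do.call(rbind, rows))
}

#' Write an ethogram to a JSON config file
#' @param eth an [ethogram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ethogram <- function(eth, path) {
  stopifnot(inherits(eth, "ethogram"))
  jsonlite::write_json(as.data.frame(eth), path, pretty = TRUE)
  invisible(path)
}
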