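#' @import methods
NULL

#' Channel schema for a mutational catalog
#'
#' A `ChannelSchema` names an ordered set of mutation channels. The built-in
#' SBS96 schema enumerates the 96 single-base-substitution classes: six
#' pyrimidine-strand substitutions (C>A, C>G, C>T, T>A, T>C, T>G) crossed with
#' the sixteen combinations of 5' and 3' flanking bases, ordered
#' substitution-major and context-lexicographic within each substitution.
#'
#' @slot name short schema identifier, e.g. `"SBS96"`.
#' @slot channels ordered character vector of unique channel labels, e.g.
#'   `"A[C>A]A"`.
#'
#' @seealso [sbs96Schema()], [substitutionOf()]
#' @export
setClass("ChannelSchema",
  representation(name = "character", channels = "character"),
  validity = function(object) {
    if (length(object@name) != 1L || !nzchar(object@name))
      return("schema name must be a single non-empty string")
    ch <- object@channels
    if (length(ch) == 0L) return("schema must define at least one channel")
    if (any(!nzchar(ch))) return("channel labels must be non-empty")
    if (anyDuplicated(ch)) return("channel labels must be unique")
    TRUE
  }
)

#' @describeIn ChannelSchema number of channels.
#' @param x,object a `ChannelSchema`.
#' @export
setMethod("length", "ChannelSchema", function(x) length(x@channels))

setMethod("show", "ChannelSchema", function(object) {
  cat(sprintf("ChannelSchema \"%s\" with %d channels\n",
              object@name, length(object@channels)))
  cat("  ", paste(utils::head(object@channels, 4L), collapse = ", "),
      if (length(object@channels) > 4L) ", ..." else "", "\n", sep = "")
})

#' Channel labels of a schema
#' @param schema a [ChannelSchema-class].
#' @return character vector of channel labels in schema order.
#' @export
channelLabels <- function(schema) {
  stopifnot(is(schema, "ChannelSchema"))
  schema@channels
}

# Pyrimidine-strand substitution classes in canonical (COSMIC) order.
SBS_SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The built-in SBS96 channel schema
#'
#' Labels take the form `"X[R>A]Y"` with `R` the pyrimidine reference base
#' (C or T), `A` the alternate base, and `X`/`Y` the 5'/3' flanking bases.
#' Ordering is substitution-major (C>A, C>G, C>T, T>A, T>C, T>G), then
#' lexicographic over the 5' and 3' context bases.
#'
#' @return a [ChannelSchema-class] with 96 channels.
#' @examples
#' length(channelLabels(sbs96Schema()))
#' @export
sbs96Schema <- function() {
  bases <- c("A", "C", "G", "T")
  labels <- unlist(lapply(SBS_SUBSTITUTIONS, function(sub) {
    as.vector(t(outer(bases, bases, function(p5, p3)
      paste0(p5, "[", sub, "]", p3))))
  }))
  new("ChannelSchema", name = "SBS96", channels = labels)
}

#' Parse SBS channel labels into their components
#'
#' @param labels character vector of labels of the form `"X[R>A]Y"`.
#' @return data.frame with columns `label`, `fivePrime`, `ref`, `alt`,
#'   `threePrime`, `substitution`.
#' @details Labels must use the pyrimidine-strand convention (reference base C
#'   or T); purine-reference labels are rejected rather than strand-folded,
#'   since folding would require the underlying variant calls.
#' @export
parseChannelLabel <- function(labels) {
  m <- regmatches(labels,
                  regexec("^([ACGT])\\[([CT])>([ACGT])\\]([ACGT])$", labels))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad))
    stop("invalid SBS channel label(s): ",
         paste(labels[bad], collapse = ", "),
         " (expected pyrimidine-strand form like \"A[C>A]A\")", call. = FALSE)
  parts <- do.call(rbind, m)
  if (any(parts[, 3L] == parts[, 4L]))
    stop("invalid SBS channel label(s): reference equals alternate in ",
         paste(labels[parts[, 3L] == parts[, 4L]], collapse = ", "),
         call. = FALSE)
  data.frame(label = parts[, 1L], fivePrime = parts[, 2L], ref = parts[, 3L],
             alt = parts[, 4L], threePrime = parts[, 5L],
             substitution = paste0(parts[, 3L], ">", parts[, 4L]),
             stringsAsFactors = FALSE)
}

#' Serialize parsed label components back into channel labels
#' @param parsed data.frame as returned by [parseChannelLabel()].
#' @return character vector of labels; inverse of [parseChannelLabel()].
#' @export
formatChannelLabel <- function(parsed) {
  paste0(parsed$fivePrime, "[", parsed$ref, ">", parsed$alt, "]",
         parsed$threePrime)
}

#' Central substitution class of channel labels
#'
#' @param schema a [ChannelSchema-class] (labels are validated against it).
#' @param labels channel labels; defaults to all channels of the schema.
#' @return character vector of substitution classes, e.g. `"C>T"`.
#' @export
substitutionOf <- function(schema, labels = channelLabels(schema)) {
  unknown <- setdiff(labels, schema@channels)
  if (length(unknown))
    stop("label(s) not in schema \"", schema@name, "\": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  parseChannelLabel(labels)$substitution
}
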