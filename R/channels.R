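#' Define a TMT channel set with group labels
#'
#' A channel set names the isobaric reporter channels of one plex and assigns
#' each channel to an experimental group. The default is the 10-plex layout of
#' the two-species spike-in benchmark: channels 126, 127N, 127C and 128N carry
#' the 1x yeast spike, 128C, 129N and 129C the 2x spike, and 130N, 130C and
#' 131 the 6x spike.
#'
#' @param labels Character vector of unique channel (tag) names.
#' @param groups Named character vector mapping every label to a group label.
#'   When `labels` is the default 10-plex and `groups` is `NULL`, the default
#'   1x/2x/6x grouping is used.
#' @return An object of class `channel_set` with elements `labels` and
#'   `groups`.
#' @examples
#' cs <- channel_set()
#' table(cs$groups)
#' @export
channel_set <- function(labels = c("126", "127N", "127C", "128N", "128C",
                                   "129N", "129C", "130N", "130C", "131"),
                        groups = NULL) {
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (is.null(groups)) {
    default10 <- c("126", "127N", "127C", "128N", "128C",
                   "129N", "129C", "130N", "130C", "131")
    if (!identical(labels, default10)) {
      stop("`groups` must be supplied for non-default channel labels")
    }
    groups <- stats::setNames(
      rep(c("1x", "2x", "6x"), times = c(4L, 3L, 3L)), labels)
  }
  if (is.null(names(groups))) {
    if (length(groups) != length(labels)) {
      stop("`groups` must be named by channel label or match `labels` length")
    }
    names(groups) <- labels
  }
  if (!setequal(names(groups), labels)) {
    stop("every channel must have exactly one group label")
  }
  structure(list(labels = labels, groups = groups[labels]),
            class = "channel_set")
}

#' @export
print.channel_set <- function(x, ...) {
  cat("<channel_set> ", length(x$labels), " channels\n", sep = "")
  print(x$groups)
  invisible(x)
}

# Internal: labels belonging to one group.
channels_in_group <- function(channels, group) {
  channels$labels[channels$groups == group]
}
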