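#' Electrode layout for the 22-channel motor-imagery grid
#'
#' The montage used throughout the package is a regular planar grid with
#' 2.5 cm pitch, centered on the Cz electrode (channel 10). Rows, from
#' anterior to posterior: Fz / FC3--FC4 / C5--C6 / CP3--CP4 / P1--Pz--P2 /
#' POz. Scalp curvature is not modeled; all distances are planar Euclidean
#' distances in centimeters.
#'
#' @param channel_ids integer channel ids, 1-based.
#' @param names standard 10-20 electrode labels, one per channel.
#' @param x_cm,y_cm planar coordinates in cm (anterior = +y, right = +x).
#' @return An object of class `electrode_layout`: a data.frame with columns
#'   `channel`, `name`, `x_cm`, `y_cm`.
#' @export
electrode_layout <- function(channel_ids, names, x_cm, y_cm) {
  channel_ids <- as.integer(channel_ids)
  stopifnot(length(channel_ids) == length(names),
            length(channel_ids) == length(x_cm),
            length(channel_ids) == length(y_cm),
            !anyDuplicated(channel_ids))
  out <- data.frame(channel = channel_ids, name = as.character(names),
                    x_cm = as.numeric(x_cm), y_cm = as.numeric(y_cm),
                    stringsAsFactors = FALSE)
  class(out) <- c("electrode_layout", "data.frame")
  out
}

#' Build the 22-electrode grid montage
#'
#' Constructs the fixed electrode arrangement of the 22-channel
#' motor-imagery acquisition montage: a regular grid with 2.5 cm spacing
#' between adjacent electrodes, Cz (channel 10) at the origin.
#'
#' Channel numbering runs row-wise from anterior to posterior:
#' \itemize{
#'   \item 1: Fz
#'   \item 2--6: FC3, FC1, FCz, FC2, FC4
#'   \item 7--13: C5, C3, C1, Cz, C2, C4, C6
#'   \item 14--18: CP3, CP1, CPz, CP2, CP4
#'   \item 19--21: P1, Pz, P2
#'   \item 22: POz
#' }
#'
#' @return An `electrode_layout` with 22 channels.
#' @examples
#' lay <- build_2a_layout()
#' pairwise_distance(lay, 9, 10)   # adjacent electrodes: 2.5 cm
#' pairwise_distance(lay, 1, 10)   # Fz to Cz: 5 cm
#' @export
build_2a_layout <- function() {
  p <- 2.5
  electrode_layout(
    channel_ids = 1:22,
    names = c("Fz",
              "FC3", "FC1", "FCz", "FC2", "FC4",
              "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
              "CP3", "CP1", "CPz", "CP2", "CP4",
              "P1", "Pz", "P2",
              "POz"),
    x_cm = p * c(0,
                 -2, -1, 0, 1, 2,
                 -3, -2, -1, 0, 1, 2, 3,
                 -2, -1, 0, 1, 2,
                 -1, 0, 1,
                 0),
    y_cm = p * c(2,
                 rep(1, 5),
                 rep(0, 7),
                 rep(-1, 5),
                 rep(-2, 3),
                 -3)
  )
}

.layout_coords <- function(layout, id) {
  i <- match(as.integer(id), layout$channel)
  if (anyNA(i)) {
    stop("unknown channel id(s): ",
         paste(id[is.na(i)], collapse = ", "), call. = FALSE)
  }
  cbind(layout$x_cm[i], layout$y_cm[i])
}

#' Euclidean distance between two electrodes
#'
#' @param layout an `electrode_layout`.
#' @param a,b channel ids.
#' @return Distance in cm; symmetric, zero iff `a == b`.
#' @export
pairwise_distance <- function(layout, a, b) {
  pa <- .layout_coords(layout, a)
  pb <- .layout_coords(layout, b)
  sqrt(sum((pa - pb)^2))
}

#' Mean distance from a set of input channels to a target channel
#'
#' Arithmetic mean of the Euclidean distances from each input electrode to
#' the target electrode. This is the "average distance" condition used when
#' comparing input-channel sets at increasing separations from the
#' completed channel.
#'
#' @param layout an `electrode_layout`.
#' @param inputs channel ids of the input set (non-empty, must not contain
#'   `target`).
#' @param target the completed channel's id.
#' @return Mean distance in cm.
#' @examples
#' lay <- build_2a_layout()
#' mean_input_distance(lay, c(1, 8, 12, 20), 10)  # 5 cm ring around Cz
#' @export
mean_input_distance <- function(layout, inputs, target) {
  if (length(inputs) == 0L) stop("'inputs' must be non-empty", call. = FALSE)
  if (target %in% inputs) {
    stop("'target' must not be one of the input channels", call. = FALSE)
  }
  mean(vapply(inputs, function(a) pairwise_distance(layout, a, target),
              numeric(1)))
}

#' Read / write an electrode layout as a delimited table
#'
#' The on-disk form is a tab-separated table with columns
#' `channel`, `name`, `x_cm`, `y_cm`. The packaged grid layout ships at
#' `system.file("extdata", "layout_2a.tsv", package = "eegcomplete")`.
#'
#' @param path file path.
#' @return `read_layout` returns an `electrode_layout`; `write_layout`
#'   returns `path` invisibly.
#' @export
read_layout <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("channel", "name", "x_cm", "y_cm")
  if (!all(need %in% names(tab))) {
    stop("layout table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  electrode_layout(tab$channel, tab$name, tab$x_cm, tab$y_cm)
}

#' @rdname read_layout
#' @param layout an `electrode_layout` to serialize.
#' @export
write_layout <- function(layout, path) {
  utils::write.table(as.data.frame(layout), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
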