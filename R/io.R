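#' Read and write photon-record files
#'
#' Photon records are tab-separated text with header
#' `channel  arrival_s  delay_ns`.
#'
#' @param path File path.
#' @param records A `pb_photons` data.frame.
#' @return `read_photons()` returns a `pb_photons` data.frame.
#' @export
read_photons <- function(path) {
    dt <- data.table::fread(path, sep = "\t", colClasses = list(
        character = "channel", numeric = c("arrival_s", "delay_ns")))
    out <- as.data.frame(dt)
    if (is.unsorted(out$arrival_s)) stop("arrival times must be non-decreasing")
    class(out) <- c("pb_photons", "data.frame")
    out
}

#' @rdname read_photons
#' @export
write_photons <- function(records, path) {
    data.table::fwrite(records[, c("channel", "arrival_s", "delay_ns")],
                       path, sep = "\t")
    invisible(path)
}

#' Read and write spectral-frame files
#'
#' Long-format tab-separated text with header `frame  lambda_nm  counts`
#' (zero-count cells may be omitted).
#'
#' @param path File path.
#' @param frames A `pb_frames` object.
#' @param frame_hz Camera frame rate used when reading.
#' @return `read_frames()` returns a `pb_frames` object.
#' @export
read_frames <- function(path, frame_hz = 50) {
    dt <- as.data.frame(data.table::fread(path, sep = "\t"))
    lam <- sort(unique(dt$lambda_nm))
    nf <- max(dt$frame)
    counts <- matrix(0L, nrow = nf, ncol = length(lam))
    counts[cbind(dt$frame, match(dt$lambda_nm, lam))] <- as.integer(dt$counts)
    structure(list(counts = counts, lambda_nm = lam, frame_hz = frame_hz),
              class = "pb_frames")
}

#' @rdname read_frames
#' @export
write_frames <- function(frames, path) {
    nz <- which(frames$counts > 0, arr.ind = TRUE)
    dt <- data.table::data.table(
        frame = nz[, 1], lambda_nm = frames$lambda_nm[nz[, 2]],
        counts = frames$counts[nz])
    data.table::setorderv(dt, c("frame", "lambda_nm"))
    data.table::fwrite(dt, path, sep = "\t")
    invisible(path)
}

#' Read and write truth sidecar files
#'
#' Tab-separated `state  start_s  end_s` tables describing ground-truth
#' trapping segments.
#'
#' @param path File path.
#' @param truth Truth data.frame.
#' @return `read_truth()` returns a data.frame.
#' @export
read_truth <- function(path) {
    as.data.frame(data.table::fread(path, sep = "\t"))
}

#' @rdname read_truth
#' @export
write_truth <- function(truth, path) {
    data.table::fwrite(truth[, c("state", "start_s", "end_s")], path, sep = "\t")
    invisible(path)
}
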