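# Filesystem watch service: the DICOM listener of the clinical deployment
# is replaced by a directory poller with the same workflow shape.  New
# NIfTI volumes dropped into the inbox are segmented automatically and the
# outputs written beside them; files already processed (by content hash)
# are skipped, unreadable files are logged and retried on a later cycle.

#' Watch a directory and segment every new volume
#'
#' @param inbox directory to poll for new \code{.nii}/\code{.nii.gz} files
#' @param library an \code{AtlasLibrary}
#' @param organs organ labels to segment (NULL = all in first atlas)
#' @param config a \code{\link{segmentationConfig}}
#' @param pollSeconds sleep between polling cycles
#' @param maxCycles stop after this many cycles (Inf = run forever); finite
#'   values make the service testable
#' @param outDir where outputs go (default: beside the input)
#' @param log function receiving status messages
#' @return invisibly, a data.frame of processed files and their hashes
#' @export
watchDirectory <- function(inbox, library, organs = NULL,
                           config = segmentationConfig(),
                           pollSeconds = 2, maxCycles = Inf,
                           outDir = NULL, log = message) {
  if (!dir.exists(inbox)) stop("inbox is not a readable directory",
                               call. = FALSE)
  # content hashes of successfully processed files persist across service
  # restarts so a re-dropped identical file is never segmented twice
  stateFile <- file.path(inbox, ".atlasseg_processed")
  seen <- if (file.exists(stateFile)) readLines(stateFile) else character()
  processed <- data.frame(file = character(), hash = character(),
                          status = character(), stringsAsFactors = FALSE)
  cycle <- 0
  while (cycle < maxCycles) {
    cycle <- cycle + 1
    files <- list.files(inbox, pattern = "\\.nii(\\.gz)?$",
                        full.names = TRUE)
    for (f in files) {
      h <- tryCatch(unname(tools::md5sum(f)), error = function(e) NA)
      if (is.na(h)) next
      if (h %in% seen) next
      log("watch: processing ", basename(f))
      ok <- tryCatch({
        patient <- readVolume(f)
        res <- segment(patient, library, organs, config)
        dst <- if (is.null(outDir))
          file.path(dirname(f), paste0(sub("\\.nii(\\.gz)?$", "",
                                           basename(f)), "_seg"))
          else outDir
        writeSegmentation(res, dst,
                          prefix = sub("\\.nii(\\.gz)?$", "", basename(f)))
        TRUE
      }, error = function(e) {
        log("watch: failed on ", basename(f), ": ", conditionMessage(e))
        FALSE
      })
      if (ok) {
        seen <- c(seen, h)   # only successful runs are deduplicated
        cat(h, file = stateFile, append = TRUE, sep = "\n")
        processed <- rbind(processed,
                           data.frame(file = f, hash = h, status = "ok"))
      } else {
        processed <- rbind(processed,
                           data.frame(file = f, hash = NA, status = "error"))
      }
    }
    if (cycle < maxCycles && pollSeconds > 0) Sys.sleep(pollSeconds)
  }
  invisible(processed)
}
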