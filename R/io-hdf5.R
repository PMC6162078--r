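# HDF5 epoch container layout
# ---------------------------
# /                       attrs: container = "erphab-epochs", version = "1"
# /<subject>_b<block>/    one group per epoch array, e.g. "s01_b03"
#     data                float64, trials x channels x samples (microvolts)
#     times               float64, seconds
#     attrs: channels (string vector), subject_id, block_id,
#            stimulated_hand, modality, trial_indices (int vector)

.h5_write_attr <- function(loc, name, value) {
  rhdf5::h5writeAttribute(value, loc, name)
}

#' Write an epoched dataset to an HDF5 container
#'
#' @param x a list of [epoch_array()] objects, or the result of
#'   [simulate_group_dataset()] (its `epochs` element is used).
#' @param path output file path (overwritten if present).
#' @return `path`, invisibly.
#' @seealso [read_dataset()] for the inverse; the file layout is documented
#'   in the function source and the package vignette.
#' @export
write_dataset <- function(x, path) {
  if (!is.null(x$epochs)) x <- x$epochs
  stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "epoch_array")))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  fid <- rhdf5::H5Fopen(path)
  .h5_write_attr(fid, "container", "erphab-epochs")
  .h5_write_attr(fid, "version", "1")
  rhdf5::H5Fclose(fid)
  for (ep in x) {
    grp <- sprintf("%s_b%02d", ep$subject_id, ep$block_id)
    rhdf5::h5createGroup(path, grp)
    rhdf5::h5write(ep$data, path, paste0(grp, "/data"))
    rhdf5::h5write(ep$times, path, paste0(grp, "/times"))
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, grp)
    .h5_write_attr(gid, "channels", ep$channels)
    .h5_write_attr(gid, "subject_id", ep$subject_id)
    .h5_write_attr(gid, "block_id", ep$block_id)
    .h5_write_attr(gid, "stimulated_hand", ep$stimulated_hand)
    .h5_write_attr(gid, "modality", ep$modality)
    .h5_write_attr(gid, "trial_indices", ep$trial_indices)
    rhdf5::H5Gclose(gid)
    rhdf5::H5Fclose(fid)
  }
  invisible(path)
}

#' Read an epoched dataset from an HDF5 container
#'
#' @param path file written by [write_dataset()].
#' @return list of [epoch_array()] objects, ordered by subject then block.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop_erphab("no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  groups <- ls$name[ls$group == "/" & ls$otype == "H5I_GROUP"]
  out <- lapply(groups, function(grp) {
    members <- ls$name[ls$group == paste0("/", grp)]
    for (need in c("data", "times")) {
      if (!need %in% members) {
        stop_erphab("group '", grp, "' is missing the '", need, "' dataset")
      }
    }
    at <- rhdf5::h5readAttributes(path, grp)
    for (need in c("channels", "subject_id", "block_id", "stimulated_hand",
                   "modality")) {
      if (is.null(at[[need]])) {
        stop_erphab("group '", grp, "' is missing the '", need, "' attribute")
      }
    }
    data <- rhdf5::h5read(path, paste0(grp, "/data"))
    times <- as.numeric(rhdf5::h5read(path, paste0(grp, "/times")))
    epoch_array(data, times, as.character(at$channels),
                subject_id = as.character(at$subject_id),
                block_id = as.integer(at$block_id),
                stimulated_hand = as.character(at$stimulated_hand),
                modality = as.character(at$modality),
                trial_indices = if (!is.null(at$trial_indices))
                  as.integer(at$trial_indices))
  })
  ord <- order(vapply(out, `[[`, "", "subject_id"),
               vapply(out, `[[`, 0L, "block_id"))
  out[ord]
}
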