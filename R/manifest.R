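# Image-stack manifests and the two-phase rename plan that performs the
# deferred-calling cycle remap on disk. Only filenames are touched; pixel
# data are never read.

#' Default image filename template
#'
#' The Genome Analyzer pipeline stores one image per (lane, tile, cycle,
#' channel) under per-cycle directories `C<cycle>.1`. The template is
#' configurable because run folders differ between pipeline versions;
#' placeholders are `{cycle}`, `{lane}`, `{tile}`, `{channel}`.
#'
#' @return The template string.
#' @export
default_image_template <- function() "C{cycle}.1/s_{lane}_{tile}_{channel}.tif"

image_path <- function(lane, tile, cycle, channel,
                       template = default_image_template()) {
  n <- max(length(lane), length(tile), length(cycle), length(channel))
  lane <- rep_len(as.character(lane), n); tile <- rep_len(as.character(tile), n)
  cycle <- rep_len(as.character(cycle), n); channel <- rep_len(as.character(channel), n)
  out <- rep.int(template, n)
  for (i in seq_len(n)) {
    p <- gsub("{cycle}", cycle[i], template, fixed = TRUE)
    p <- gsub("{lane}", lane[i], p, fixed = TRUE)
    p <- gsub("{tile}", tile[i], p, fixed = TRUE)
    out[i] <- gsub("{channel}", channel[i], p, fixed = TRUE)
  }
  out
}

template_regex <- function(template = default_image_template()) {
  rx <- gsub("([][(){}.*+?^$|\\\\-])", "\\\\\\1", template, perl = TRUE)
  rx <- sub("\\\\\\{cycle\\\\\\}", "(?<cycle>[0-9]+)", rx)
  rx <- sub("\\\\\\{lane\\\\\\}", "(?<lane>[0-9]+)", rx)
  rx <- sub("\\\\\\{tile\\\\\\}", "(?<tile>[0-9]+)", rx)
  rx <- sub("\\\\\\{channel\\\\\\}", "(?<channel>[acgt])", rx)
  paste0("^", rx, "$")
}

#' Scan a run directory for image files
#'
#' Builds an image manifest by matching every file under `root` against
#' the filename template. Entries are unique in (lane, tile, cycle,
#' channel); paths are relative to `root`.
#'
#' @param root run directory.
#' @param template filename template (see [default_image_template()]).
#' @return A data.frame of class `"image_manifest"` with columns `lane`,
#'   `tile`, `cycle`, `channel`, `path`.
#' @export
scan_image_manifest <- function(root, template = default_image_template()) {
  if (!dir.exists(root)) stop(sprintf("run directory '%s' not found", root), call. = FALSE)
  files <- list.files(root, recursive = TRUE, full.names = FALSE)
  rx <- template_regex(template)
  m <- regexpr(rx, files, perl = TRUE)
  hit <- which(m != -1L)
  if (length(hit) == 0L) {
    mf <- data.frame(lane = integer(), tile = integer(), cycle = integer(),
                     channel = character(), path = character(),
                     stringsAsFactors = FALSE)
  } else {
    capt <- function(name) {
      st <- attr(m, "capture.start")[hit, name]
      len <- attr(m, "capture.length")[hit, name]
      substr(files[hit], st, st + len - 1L)
    }
    mf <- data.frame(lane = as.integer(capt("lane")),
                     tile = as.integer(capt("tile")),
                     cycle = as.integer(capt("cycle")),
                     channel = capt("channel"),
                     path = files[hit],
                     stringsAsFactors = FALSE)
    mf <- mf[order(mf$lane, mf$tile, mf$cycle, mf$channel), , drop = FALSE]
    rownames(mf) <- NULL
    if (anyDuplicated(mf[c("lane", "tile", "cycle", "channel")])) {
      stop("duplicate (lane, tile, cycle, channel) entries in run directory",
           call. = FALSE)
    }
  }
  attr(mf, "root") <- root
  attr(mf, "template") <- template
  class(mf) <- c("image_manifest", "data.frame")
  mf
}

#' Check an image manifest for completeness
#'
#' A complete manifest has all four channels (a, c, g, t) for every
#' (lane, tile, cycle) combination present.
#'
#' @param manifest an [scan_image_manifest()] result.
#' @return A data.frame of missing (lane, tile, cycle, channel) rows
#'   (zero rows when complete).
#' @export
manifest_missing <- function(manifest) {
  stopifnot(inherits(manifest, "image_manifest"))
  if (nrow(manifest) == 0L) {
    return(data.frame(lane = integer(), tile = integer(), cycle = integer(),
                      channel = character(), stringsAsFactors = FALSE))
  }
  keys <- unique(manifest[c("lane", "tile", "cycle")])
  full <- merge(keys, data.frame(channel = c("a", "c", "g", "t")))
  have <- paste(manifest$lane, manifest$tile, manifest$cycle, manifest$channel)
  miss <- full[!paste(full$lane, full$tile, full$cycle, full$channel) %in% have, ,
               drop = FALSE]
  rownames(miss) <- NULL
  miss
}

#' Plan the cycle-remap renaming of an image manifest
#'
#' Produces an ordered two-phase rename plan whose execution relabels
#' every image file's cycle through the remap. Phase 1 moves each file to
#' a unique temporary name; phase 2 moves temporaries to final names, so
#' no intermediate state ever has two files contending for one path.
#' No-op moves (identity-mapped files) are omitted.
#'
#' Incomplete cycle sets are rejected unless `allow_incomplete = TRUE`
#' (the missing files are listed in the error).
#'
#' @param manifest an [scan_image_manifest()] result.
#' @param remap a [build_remap()] result; all manifest cycles must lie in
#'   `1..remap$N`.
#' @param allow_incomplete proceed even if channels are missing.
#' @return A data.frame of class `"rename_plan"` with columns `old_path`,
#'   `tmp_path`, `new_path` (paths relative to the manifest root).
#' @seealso [execute_rename_plan()]
#' @export
plan_rename <- function(manifest, remap, allow_incomplete = FALSE) {
  stopifnot(inherits(manifest, "image_manifest"), inherits(remap, "cycle_remap"))
  if (nrow(manifest) && any(manifest$cycle < 1L | manifest$cycle > remap$N)) {
    stop(sprintf("manifest contains cycles outside 1..%d", remap$N), call. = FALSE)
  }
  miss <- manifest_missing(manifest)
  if (nrow(miss) && !allow_incomplete) {
    stop(sprintf("incomplete manifest: %d missing file(s), e.g. lane %d tile %d cycle %d channel %s",
                 nrow(miss), miss$lane[1], miss$tile[1], miss$cycle[1], miss$channel[1]),
         call. = FALSE)
  }
  template <- attr(manifest, "template")
  if (is.null(template)) template <- default_image_template()
  new_cycle <- remap$mapping[manifest$cycle]
  new_path <- image_path(manifest$lane, manifest$tile, new_cycle,
                         manifest$channel, template)
  changed <- new_path != manifest$path
  plan <- data.frame(old_path = manifest$path[changed],
                     new_path = new_path[changed],
                     stringsAsFactors = FALSE)
  plan$tmp_path <- vapply(plan$old_path, paste0, character(1), ".remap-tmp",
                          USE.NAMES = FALSE)
  plan <- plan[c("old_path", "tmp_path", "new_path")]
  if (anyDuplicated(plan$new_path)) {
    stop("rename plan has colliding target paths", call. = FALSE)
  }
  clash <- setdiff(intersect(plan$new_path, manifest$path),
                   plan$old_path)
  if (length(clash)) {
    stop(sprintf("target path '%s' is occupied by a file outside the plan", clash[1L]),
         call. = FALSE)
  }
  attr(plan, "root") <- attr(manifest, "root")
  class(plan) <- c("rename_plan", "data.frame")
  plan
}

#' @export
print.rename_plan <- function(x, ...) {
  if (nrow(x) == 0L) cat("Rename plan: zero changes\n")
  else cat(sprintf("Rename plan: %d file move(s) (two-phase via *.remap-tmp)\n", nrow(x)))
  invisible(x)
}

#' Execute (or dry-run) a rename plan
#'
#' Dry run is the default: the plan is printed and nothing is touched.
#' With `execute = TRUE`, phase 1 renames every `old_path` to its
#' `tmp_path` and phase 2 renames temporaries to final paths, creating
#' target directories as needed. Each move is a single `file.rename`.
#' A run interrupted during phase 1 is detectable (temporary `*.remap-tmp`
#' names remain) and resumable: rows whose `old_path` is gone but whose
#' `tmp_path` exists are treated as already phase-1 complete.
#'
#' @param plan a [plan_rename()] result.
#' @param root run directory the plan's relative paths refer to; defaults
#'   to the root recorded when the manifest was scanned.
#' @param execute actually perform the renames (default `FALSE`).
#' @return Invisibly, the number of files moved (0 for a dry run).
#' @export
execute_rename_plan <- function(plan, root = attr(plan, "root"), execute = FALSE) {
  stopifnot(inherits(plan, "rename_plan"))
  if (!execute) {
    if (nrow(plan) == 0L) message("dry run: zero changes")
    else message(sprintf("dry run: %d file move(s) planned; rerun with execute = TRUE",
                         nrow(plan)))
    return(invisible(0L))
  }
  if (is.null(root)) stop("no run directory recorded; pass 'root'", call. = FALSE)
  old <- file.path(root, plan$old_path)
  tmp <- file.path(root, plan$tmp_path)
  new <- file.path(root, plan$new_path)
  for (i in seq_len(nrow(plan))) {
    if (file.exists(old[i])) {
      if (!file.rename(old[i], tmp[i])) {
        stop(sprintf("phase 1 rename failed: %s", plan$old_path[i]), call. = FALSE)
      }
    } else if (!file.exists(tmp[i])) {
      stop(sprintf("missing file: neither '%s' nor its temporary exists",
                   plan$old_path[i]), call. = FALSE)
    }
  }
  for (i in seq_len(nrow(plan))) {
    dir.create(dirname(new[i]), recursive = TRUE, showWarnings = FALSE)
    if (!file.rename(tmp[i], new[i])) {
      stop(sprintf("phase 2 rename failed: %s", plan$new_path[i]), call. = FALSE)
    }
  }
  invisible(nrow(plan))
}
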