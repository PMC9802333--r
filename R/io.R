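# Trajectory and model serialization: extended-XYZ trajectories (one frame
# per step, per-atom pos/vel/accel/mass/charge columns, per-frame comment
# fields for dt, law constants and the periodic box), JSON model
# checkpoints with an embedded feature-layout descriptor, and experiment
# manifests.

.fmt <- function(x) sprintf("%.17g", x)

#' Write a trajectory as extended XYZ
#'
#' One frame per time step; the comment line carries
#' `Properties=species:S:1:pos:R:d:vel:R:d:accel:R:d:mass:R:1:charge:R:1`
#' plus `dt`, `step`, `law`, the law constants (`const_*`), the provenance
#' flag and (for periodic systems) `box`. Numeric fields are written with
#' 17 significant digits so a round trip is lossless to double precision.
#'
#' @param traj A `trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  dm <- dim(traj$positions)
  T <- dm[1]; n <- dm[2]; d <- dm[3]
  species <- if (traj$spec$law == "lj") "Ar" else "P"
  cs <- traj$spec$constants
  const_str <- paste(sprintf("const_%s=%s", names(cs), .fmt(unlist(cs))),
                     collapse = " ")
  props <- sprintf("Properties=species:S:1:pos:R:%d:vel:R:%d:accel:R:%d:mass:R:1:charge:R:1",
                   d, d, d)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seq_len(T)) {
    header <- sprintf('%s dt=%s step=%d law=%s dim=%d provenance=%s %s%s',
                      props, .fmt(traj$dt), s, traj$spec$law, d,
                      traj$provenance, const_str,
                      if (!is.null(traj$box)) paste0(" box=", .fmt(traj$box)) else "")
    block <- cbind(matrix(traj$positions[s, , ], n),
                   matrix(traj$velocities[s, , ], n),
                   matrix(traj$accelerations[s, , ], n),
                   traj$masses, traj$charges)
    lines <- paste(species, apply(block, 1, function(r) paste(.fmt(r), collapse = " ")))
    writeLines(c(as.character(n), header, lines), con)
  }
  invisible(path)
}

# split a comment line on whitespace, honouring double quotes
.tokenize_kv <- function(line) {
  toks <- regmatches(line, gregexpr('[^ "]+="[^"]*"|[^ ]+', line))[[1]]
  kv <- strsplit(toks, "=", fixed = TRUE)
  vals <- vapply(kv, function(p) gsub('"', "", paste(p[-1], collapse = "=")), "")
  stats::setNames(vals, vapply(kv, `[[`, "", 1))
}

#' Read an extended-XYZ trajectory written by [write_extxyz()]
#'
#' @param path File path.
#' @return A `trajectory`.
#' @export
read_extxyz <- function(path) {
  lines <- readLines(path)
  pos <- 1L
  frames <- list()
  header <- NULL
  while (pos <= length(lines)) {
    n <- as.integer(lines[pos])
    header <- .tokenize_kv(lines[pos + 1L])
    d <- as.integer(header[["dim"]])
    body <- lines[pos + 1L + seq_len(n)]
    vals <- matrix(as.numeric(unlist(lapply(strsplit(trimws(body), " +"),
                                            `[`, -1L))),
                   nrow = n, byrow = TRUE)
    frames[[length(frames) + 1L]] <- vals
    pos <- pos + 2L + n
  }
  d <- as.integer(header[["dim"]])
  law <- header[["law"]]
  cn <- names(header)[startsWith(names(header), "const_")]
  consts <- as.list(as.numeric(header[cn]))
  names(consts) <- sub("^const_", "", cn)
  spec <- do.call(system_spec, c(list(law = law, d = d), consts))
  T <- length(frames)
  n <- nrow(frames[[1]])
  arr <- function(cols) {
    a <- array(NA_real_, c(T, n, d))
    for (s in seq_len(T)) a[s, , ] <- frames[[s]][, cols, drop = FALSE]
    a
  }
  structure(list(positions = arr(1:d),
                 velocities = arr(d + 1:d),
                 accelerations = arr(2 * d + 1:d),
                 charges = frames[[1]][, 3 * d + 2],
                 masses = frames[[1]][, 3 * d + 1],
                 dt = as.numeric(header[["dt"]]),
                 spec = spec,
                 provenance = header[["provenance"]],
                 box = if ("box" %in% names(header))
                   as.numeric(header[["box"]]) else NULL),
            class = "trajectory")
}

#' Save a fitted model as a portable JSON checkpoint
#'
#' Stores the mode, variant, activation, feature-layout descriptor,
#' configuration, training history and all parameter tensors at full
#' precision. [read_checkpoint()] refuses nothing by itself, but
#' [predict.pignpi()] rejects graphs whose layout does not match the
#' embedded descriptor.
#'
#' @param object A `pignpi` model.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "pignpi"))
  if (inherits(object, "pignpi_closed"))
    stop("closed-form oracle models need no checkpoint")
  payload <- list(
    package = "pignpi",
    format = 1L,
    mode = object$mode,
    variant = object$variant,
    activation = object$activation,
    layout = unclass(object$layout)[c("d", "has_charge", "has_disp")],
    config = object$config,
    alpha = object$alpha %||% 0,
    kinematics = object$kinematics %||% "fd",
    edge = object$edge,
    node = object$node,
    w = object$w,
    best_epoch = object$best_epoch,
    history = object$history,
    split = object$split)
  # 17 significant digits: doubles survive the text round trip exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Load a model checkpoint written by [write_checkpoint()]
#'
#' @param path Checkpoint path.
#' @return A `pignpi` model.
#' @export
read_checkpoint <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (!identical(p$package, "pignpi")) stop("not a pignpi checkpoint")
  lay <- feature_layout(p$layout$d, p$layout$has_charge, p$layout$has_disp)
  fixnet <- function(net) {
    if (is.null(net)) return(NULL)
    list(W = lapply(net$W, function(m) matrix(unlist(m), nrow = nrow(m))),
         b = lapply(net$b, as.numeric))
  }
  structure(list(mode = p$mode, variant = p$variant, layout = lay,
                 edge = fixnet(p$edge), node = fixnet(p$node),
                 w = if (is.null(p$w)) NULL else as.numeric(p$w),
                 activation = p$activation,
                 config = p$config, alpha = p$alpha,
                 kinematics = p$kinematics,
                 history = if (is.null(p$history)) NULL else as.data.frame(p$history),
                 best_epoch = p$best_epoch,
                 split = p$split, spec = NULL),
            class = "pignpi")
}

#' Write an experiment manifest
#'
#' A JSON record from which a run can be regenerated: package version,
#' system spec, simulation, split and training configuration, and seeds.
#'
#' @param x Named list of configuration entries.
#' @param path Output path.
#' @export
write_manifest <- function(x, path) {
  x$package <- "pignpi"
  x$version <- as.character(utils::packageVersion("pignpi"))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) jsonlite::fromJSON(path)
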