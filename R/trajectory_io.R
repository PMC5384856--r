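# Multi-frame trajectory I/O in two plain-text dialects.
#
# XYZ dialect: per frame an atom-count line, then a comment line
# "shellfield frame=<i> temperature=<T>", then one "<name> x y z" line per
# site. Water sites are named O, H1, H2, L1, L2 and appear as consecutive
# five-site groups; any other names are looked up in the solute geometry.
#
# PDB dialect: MODEL/ENDMDL blocks; waters are residue HOH with atom names
# O/H1/H2/L1/L2, the solute is residue DMP (resSeq 0). Coordinates carry
# the formats' printed precision (1e-4 A for XYZ as written here, 1e-3 A
# for PDB).

WATER_SITE_NAMES <- c("O", "H1", "H2", "L1", "L2")

#' Write a trajectory to XYZ or PDB
#'
#' @param traj A trajectory tibble in site-record form.
#' @param path Output file path.
#' @param format `"xyz"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_frames <- function(traj, path, format = c("xyz", "pdb")) {
  format <- match.arg(format)
  temp <- attr(traj, "temperature")
  if (is.null(temp)) temp <- NA_real_
  frames <- trajectory_split(traj)
  con <- file(path, "w")
  on.exit(close(con))
  for (fd in frames) {
    fi <- fd$frame[1]
    if (format == "xyz") {
      writeLines(as.character(nrow(fd)), con)
      writeLines(sprintf("shellfield frame=%d temperature=%s", fi,
                         format(temp)), con)
      writeLines(sprintf("%-4s %12.4f %12.4f %12.4f", fd$site, fd$x, fd$y,
                         fd$z), con)
    } else {
      writeLines(sprintf("MODEL     %4d", fi), con)
      if (fi == frames[[1]]$frame[1] && !is.na(temp)) {
        writeLines(sprintf("REMARK 250 TEMPERATURE %s K", format(temp)), con)
      }
      resname <- ifelse(fd$species == "water", "HOH", "DMP")
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s  %4d    %8.3f%8.3f%8.3f  1.00  0.00",
        seq_len(nrow(fd)), fd$site, resname, fd$molecule, fd$x, fd$y, fd$z),
        con)
      writeLines("ENDMDL", con)
    }
  }
  invisible(path)
}

io_error <- function(line, msg) {
  stop(sprintf("trajectory format error at line %d: %s", line, msg),
       call. = FALSE)
}

#' Read a multi-frame trajectory from XYZ or PDB
#'
#' Site charges are re-attached from the water model (water sites) and the
#' solute geometry (other atom names); an atom name known to neither is a
#' format error reporting the offending line.
#'
#' @param path Input file.
#' @param format `"xyz"` or `"pdb"`.
#' @param solute Solute geometry used to resolve non-water atom names.
#' @param model Water model used for water site charges.
#' @return A `shell_trajectory` tibble.
#' @export
read_frames <- function(path, format = c("xyz", "pdb"), solute = dmp_solute(),
                        model = water_model()) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    io_error(1L, "empty file")
  }
  temp <- NA_real_
  recs <- list()
  if (format == "xyz") {
    i <- 1L
    fi <- 0L
    while (i <= length(lines)) {
      if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
      n <- suppressWarnings(as.integer(trimws(lines[i])))
      if (is.na(n) || n < 1) io_error(i, "expected an atom count")
      if (i + 1L + n > length(lines)) io_error(i, "truncated frame")
      fi <- fi + 1L
      cm <- lines[i + 1L]
      tm <- regmatches(cm, regexec("temperature=([-0-9.eE]+)", cm))[[1]]
      if (length(tm) == 2) temp <- as.numeric(tm[2])
      at <- lines[(i + 2L):(i + 1L + n)]
      parts <- strsplit(trimws(at), "\\s+")
      bad <- which(vapply(parts, length, 0L) < 4L)
      if (length(bad)) io_error(i + 1L + bad[1], "expected 'name x y z'")
      recs[[fi]] <- tibble::tibble(
        frame = fi,
        site = vapply(parts, `[`, "", 1L),
        x = as.numeric(vapply(parts, `[`, "", 2L)),
        y = as.numeric(vapply(parts, `[`, "", 3L)),
        z = as.numeric(vapply(parts, `[`, "", 4L)),
        line = (i + 2L):(i + 1L + n)
      )
      i <- i + 2L + n
    }
  } else {
    fi <- 0L
    cur <- NULL
    for (i in seq_along(lines)) {
      ln <- lines[i]
      if (startsWith(ln, "MODEL")) {
        fi <- fi + 1L
        cur <- list()
      } else if (startsWith(ln, "REMARK 250 TEMPERATURE")) {
        temp <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]][4])
      } else if (startsWith(ln, "ATOM") || startsWith(ln, "HETATM")) {
        if (is.null(cur)) io_error(i, "ATOM record outside MODEL block")
        cur[[length(cur) + 1L]] <- tibble::tibble(
          frame = fi,
          site = trimws(substr(ln, 13, 16)),
          x = as.numeric(substr(ln, 31, 38)),
          y = as.numeric(substr(ln, 39, 46)),
          z = as.numeric(substr(ln, 47, 54)),
          line = i
        )
      } else if (startsWith(ln, "ENDMDL")) {
        recs[[fi]] <- dplyr::bind_rows(cur)
        cur <- NULL
      }
    }
    if (!is.null(cur) && length(cur)) recs[[fi]] <- dplyr::bind_rows(cur)
    if (length(recs) == 0) io_error(1L, "no MODEL/ATOM records found")
  }

  parse_frame <- function(df) {
    is_w <- df$site %in% WATER_SITE_NAMES
    sol <- df[!is_w, ]
    if (nrow(sol) > 0) {
      unknown <- !(sol$site %in% solute$atoms$label)
      if (any(unknown)) {
        io_error(sol$line[which(unknown)[1]],
                 sprintf("unknown atom label '%s'", sol$site[which(unknown)[1]]))
      }
      sol$charge <- solute$atoms$charge[match(sol$site, solute$atoms$label)]
      sol$species <- "solute"
      sol$molecule <- 0L
    }
    w <- df[is_w, ]
    if (nrow(w) %% 5L != 0L ||
        !all(w$site == rep(WATER_SITE_NAMES, nrow(w) / 5L))) {
      io_error(w$line[1],
               "water sites must appear as consecutive O,H1,H2,L1,L2 groups")
    }
    if (nrow(w) > 0) {
      w$molecule <- rep(seq_len(nrow(w) / 5L), each = 5L)
      w$charge <- rep(model$sites$charge, nrow(w) / 5L)
      w$species <- "water"
    }
    out <- dplyr::bind_rows(sol, w)
    out[, c("frame", "species", "molecule", "site", "x", "y", "z", "charge")]
  }
  frames <- lapply(recs, parse_frame)
  nwat <- vapply(frames, function(f) sum(f$species == "water") / 5L, 0)
  if (length(unique(nwat)) > 1L) {
    io_error(1L, sprintf("inconsistent water count across frames (%s)",
                         paste(unique(nwat), collapse = ", ")))
  }
  new_trajectory(dplyr::bind_rows(frames), temp, NULL,
                 if (any(frames[[1]]$species == "solute")) solute else NULL,
                 model)
}
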