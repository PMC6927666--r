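#' Read a grayscale TIFF stack and bind channels to roles
#'
#' Reads a single- or multi-page 8/16-bit grayscale TIFF and binds each page
#' to a declared channel role (`dapi`, `pla`, `membrane`, ...). Intensities
#' are returned as raw counts at the stored bit depth (no rescaling).
#'
#' @param path TIFF file path.
#' @param channel_manifest Character vector of roles, one per page in page
#'   order, e.g. `c("dapi", "pla")`.
#' @param pixel_size Optional physical pixel size (um) attached to every
#'   channel.
#' @return Named list mapping each role to an [image2d()].
#' @export
read_image_stack <- function(path, channel_manifest, pixel_size = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(channel_manifest) > length(pages))
    stop(sprintf("format error: manifest declares %d channel role(s) but the TIFF has %d page(s)",
                 length(channel_manifest), length(pages)), call. = FALSE)
  out <- list()
  for (i in seq_along(channel_manifest)) {
    pg <- pages[[i]]
    if (length(dim(pg)) == 3L) {
      if (dim(pg)[3] == 1L) pg <- pg[, , 1]
      else stop("format error: RGB/multi-sample page without a declared conversion",
                call. = FALSE)
    }
    out[[channel_manifest[i]]] <-
      image2d(pg, pixel_size = pixel_size, channel = channel_manifest[i])
  }
  out
}

#' Write a grayscale image, mask or label map as 16-bit TIFF
#'
#' Integer-valued content up to 65535 (channels, masks, label maps) is
#' written losslessly as 16-bit grayscale TIFF. Continuous-valued maps
#' (e.g. QI modulus maps, where failed pixels are `NA`) go through
#' [write_matrix_tsv()] instead, which preserves missing values exactly.
#'
#' @param x An [image2d()], [label_map()], mask or numeric matrix with
#'   non-negative integer values below 2^16.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(x, path) {
  p <- pixels_of(x)
  storage.mode(p) <- "double"
  if (!all(is.finite(p)) || any(p < 0) || any(p != round(p)) ||
      max(p) > 65535)
    stop("16-bit TIFF output needs integer values in [0, 65535]",
         call. = FALSE)
  tiff::writeTIFF(p / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write / read a numeric matrix as a TSV raster
#'
#' Plain-text raster interchange for continuous-valued maps (Young's
#' modulus, contact height): one row per matrix row, `NA` marks failed
#' pixels. Deterministic output for deterministic input.
#'
#' @param m Numeric matrix.
#' @param path File path.
#' @return `path` (write) or the matrix (read).
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' Read a force curve (or QI grid) from a plain-text table
#'
#' The format is a TSV with a metadata header of `# key = value` lines
#' (`k`, `sensitivity`, `segment`, `geometry`, plus `R`/`half_angle`/`nu`
#' for the probe and `deflection_unit`) followed by columns `z_nm` and
#' `deflection`; a grid file carries additional `row` and `col` columns and
#' yields one curve per pixel.
#'
#' @param path File path.
#' @return A [force_curve()], or a `qi_grid`-shaped list when `row`/`col`
#'   columns are present.
#' @export
read_force_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=")[[1]]
    if (length(kv) == 2)
      meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  num <- function(name) if (is.null(meta[[name]])) NULL
                        else as.numeric(meta[[name]])
  if (is.null(meta$k))
    stop("format error: missing spring constant k in metadata", call. = FALSE)
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t")
  if (!all(c("z_nm", "deflection") %in% names(tab)))
    stop("format error: need z_nm and deflection columns", call. = FALSE)
  probe <- NULL
  if (!is.null(meta$geometry)) {
    probe <- if (meta$geometry == "sphere")
      probe_spec("sphere", R = num("R"),
                 nu = if (is.null(num("nu"))) 0.5 else num("nu"))
    else
      probe_spec("cone", half_angle = num("half_angle"),
                 nu = if (is.null(num("nu"))) 0.5 else num("nu"))
  }
  mk <- function(sub) {
    force_curve(z = sub$z_nm, deflection = sub$deflection, k = num("k"),
                sensitivity = num("sensitivity"),
                segment = if (is.null(meta$segment)) "approach"
                          else meta$segment,
                probe = probe,
                deflection_unit = if (is.null(meta$deflection_unit)) "V"
                                  else meta$deflection_unit)
  }
  if (all(c("row", "col") %in% names(tab))) {
    nr <- max(tab$row); nc <- max(tab$col)
    curves <- vector("list", nr * nc)
    for (c in seq_len(nc)) for (r in seq_len(nr)) {
      sub <- tab[tab$row == r & tab$col == c, , drop = FALSE]
      if (nrow(sub) == 0)
        stop("format error: missing curve for pixel (", r, ",", c, ")",
             call. = FALSE)
      curves[[(c - 1L) * nr + r]] <- mk(sub)
    }
    structure(list(curves = curves, nrow = nr, ncol = nc,
                   scan_size_um = num("scan_size_um")),
              class = "qi_grid")
  } else {
    mk(tab)
  }
}

#' Write a force curve (or QI grid) as a plain-text table
#'
#' Inverse of [read_force_table()].
#'
#' @param x A [force_curve()] or `qi_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_force_table <- function(x, path) {
  hdr_of <- function(curve, extra = character()) {
    h <- c(sprintf("# k = %.10g", curve$k),
           if (!is.null(curve$sensitivity))
             sprintf("# sensitivity = %.10g", curve$sensitivity),
           sprintf("# segment = %s", curve$segment),
           sprintf("# deflection_unit = %s", curve$deflection_unit))
    if (!is.null(curve$probe)) {
      p <- curve$probe
      h <- c(h, sprintf("# geometry = %s", p$geometry),
             if (!is.null(p$R)) sprintf("# R = %.10g", p$R),
             if (!is.null(p$half_angle))
               sprintf("# half_angle = %.10g", p$half_angle),
             sprintf("# nu = %.10g", p$nu))
    }
    c(h, extra)
  }
  if (inherits(x, "force_curve")) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(hdr_of(x), con)
    writeLines("z_nm\tdeflection", con)
    writeLines(sprintf("%.10g\t%.10g", x$z, x$deflection), con)
  } else if (inherits(x, "qi_grid")) {
    con <- file(path, "w"); on.exit(close(con))
    extra <- if (!is.null(x$scan_size_um))
      sprintf("# scan_size_um = %.10g", x$scan_size_um[1]) else character()
    writeLines(hdr_of(x$curves[[1]], extra), con)
    writeLines("row\tcol\tz_nm\tdeflection", con)
    for (c in seq_len(x$ncol)) for (r in seq_len(x$nrow)) {
      cur <- x$curves[[(c - 1L) * x$nrow + r]]
      writeLines(sprintf("%d\t%d\t%.10g\t%.10g", r, c, cur$z,
                         cur$deflection), con)
    }
  } else stop("cannot write object of class ", class(x)[1], call. = FALSE)
  invisible(path)
}

#' Write pipeline results to an output directory
#'
#' Emits CSV tables with stable column order, TSV rasters for continuous
#' maps (`NA` marks failed pixels), and a JSON run manifest capturing the
#' configuration, seed and package version, so a run is exactly
#' reproducible from its outputs.
#'
#' @param results A `pla_result` list / batch summary (from
#'   [summarize_pla_batch()]), a [summarize_cfs()] result, or a `qi_map`.
#' @param out_dir Output directory (created if needed).
#' @param config Optional configuration list echoed into the manifest.
#' @param seed Optional seed echoed into the manifest.
#' @return Character vector of written file paths, invisibly.
#' @export
write_results <- function(results, out_dir, config = NULL, seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  written <- character()
  emit_csv <- function(df, name) {
    f <- file.path(out_dir, name)
    utils::write.csv(df, f, row.names = FALSE)
    written <<- c(written, f)
  }
  if (inherits(results, "qi_map")) {
    fE <- file.path(out_dir, "qi_modulus_Pa.tsv")
    fH <- file.path(out_dir, "qi_height_nm.tsv")
    write_matrix_tsv(results$E, fE)
    write_matrix_tsv(results$height_nm, fH)
    written <- c(written, fE, fH)
  } else if (is.list(results) && !is.null(results$per_image)) {
    emit_csv(results$per_image, "pla_per_image.csv")
    emit_csv(results$per_condition, "pla_per_condition.csv")
  } else if (is.list(results) && !is.null(results$summary)) {
    emit_csv(results$summary, "cfs_summary.csv")
    if (!is.null(results$ratios)) emit_csv(results$ratios, "cfs_ratios.csv")
  } else if (inherits(results, "pla_result")) {
    df <- data.frame(image_id = if (is.null(results$image_id)) "img001"
                                else results$image_id,
                     n_nuclei = results$n_nuclei,
                     n_nuclear = results$n_nuclear,
                     n_cytosolic = results$n_cytosolic,
                     n_total = results$n_total,
                     ratio_nuc_cyt = results$ratio_nuc_cyt)
    emit_csv(df, "pla_per_image.csv")
  } else stop("unsupported results object", call. = FALSE)
  manifest <- list(package = "plamech",
                   version = as.character(utils::packageVersion("plamech")),
                   written = basename(written),
                   config = config, seed = seed)
  fm <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, fm, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  written <- c(written, fm)
  invisible(written)
}
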