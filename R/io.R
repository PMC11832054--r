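# NIfTI and report I/O. Volumes travel as NIfTI-1; complex GREs as paired
# real/imaginary files `<stem>_real.nii.gz` / `<stem>_imag.nii.gz`.

# Read a NIfTI volume as a plain numeric array (image metadata dropped, so
# simulated volumes round-trip to identical R objects).
.read_vol <- function(path) {
  img <- RNifti::readNifti(path)
  out <- as.vector(img)
  dim(out) <- dim(img)
  out
}

#' Write a complex GRE volume as a real/imaginary NIfTI pair
#'
#' @param gre complex array.
#' @param stem output path stem (no extension).
#' @return The two paths, invisibly.
#' @export
write_gre_pair <- function(gre, stem) {
  pr <- paste0(stem, "_real.nii.gz")
  pi <- paste0(stem, "_imag.nii.gz")
  RNifti::writeNifti(array(Re(gre), dim(gre)), pr)
  RNifti::writeNifti(array(Im(gre), dim(gre)), pi)
  invisible(c(pr, pi))
}

#' Read a complex GRE volume from a real/imaginary NIfTI pair
#'
#' @param stem path stem written by [write_gre_pair()].
#' @return Complex array.
#' @export
read_gre_pair <- function(stem) {
  re <- .read_vol(paste0(stem, "_real.nii.gz"))
  im <- .read_vol(paste0(stem, "_imag.nii.gz"))
  if (!identical(dim(re), dim(im)))
    stop_mapt1("real/imaginary volumes of %s disagree in shape", stem)
  g <- complex(real = re, imaginary = im)
  dim(g) <- dim(re)
  g
}

#' Write a T1 map result as NIfTI volumes
#'
#' Writes `<stem>_t1.nii.gz`, `<stem>_mask.nii.gz` and, when present,
#' `<stem>_sigma.nii.gz` (NA encoded as 0 within the masked-out region), plus
#' a JSON sidecar recording the method tag.
#'
#' @param x a `t1_map`.
#' @param stem output path stem.
#' @return The paths written, invisibly.
#' @export
write_t1_map <- function(x, stem) {
  t1 <- x$t1_s; t1[!x$valid_mask] <- 0
  paths <- paste0(stem, "_t1.nii.gz")
  RNifti::writeNifti(t1, paths)
  mp <- paste0(stem, "_mask.nii.gz")
  RNifti::writeNifti(array(as.integer(x$valid_mask), dim(x$valid_mask)), mp)
  paths <- c(paths, mp)
  if (!is.null(x$sigma_t1_s)) {
    sg <- x$sigma_t1_s; sg[!x$valid_mask] <- 0
    sp <- paste0(stem, "_sigma.nii.gz")
    RNifti::writeNifti(sg, sp)
    paths <- c(paths, sp)
  }
  side <- paste0(stem, ".json")
  jsonlite::write_json(list(method = x$method,
                            n_valid = sum(x$valid_mask)),
                       side, auto_unbox = TRUE)
  invisible(c(paths, side))
}

#' Read a T1 map written by [write_t1_map()]
#' @param stem path stem.
#' @return A `t1_map`.
#' @export
read_t1_map <- function(stem) {
  t1 <- .read_vol(paste0(stem, "_t1.nii.gz"))
  mask <- .read_vol(paste0(stem, "_mask.nii.gz")) > 0
  sp <- paste0(stem, "_sigma.nii.gz")
  sg <- if (file.exists(sp)) .read_vol(sp) else NULL
  meta <- jsonlite::read_json(paste0(stem, ".json"))
  new_t1_map(t1, mask, meta$method, sigma = sg)
}

#' Write a phantom cohort to disk with a manifest
#'
#' Per subject: labels, true T1, B1 (NIfTI), GREs (real/imag pairs), optional
#' 4-D SIR stack, IR-reference and biased MP2RAGE-side maps, listed in
#' `manifest.json` together with the generating seed.
#'
#' @param subjects list from [synth_subjects()].
#' @param dir output directory (created).
#' @param spec the generating [phantom_spec()].
#' @return Manifest path, invisibly.
#' @export
write_subjects <- function(subjects, dir, spec) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (sub in subjects) {
    tag <- sprintf("sub%02d", sub$subject)
    paths <- list()
    wr <- function(vol, name) {
      p <- file.path(dir, paste0(tag, "_", name, ".nii.gz"))
      v <- vol; v[!is.finite(v)] <- 0
      RNifti::writeNifti(v, p)
      p
    }
    paths$labels <- wr(array(as.numeric(sub$labels), dim(sub$labels)), "labels")
    paths$true_t1 <- wr(sub$true_t1, "truet1")
    paths$b1 <- wr(sub$b1, "b1")
    paths$ir_t1 <- wr(sub$ir_t1, "ir")
    paths$mp2rage_biased <- wr(sub$mp2rage_biased, "biased")
    paths$gres <- vapply(seq_along(sub$gres), function(k) {
      stem <- file.path(dir, sprintf("%s_gre%d", tag, k))
      write_gre_pair(sub$gres[[k]], stem)
      stem
    }, character(1))
    if (!is.null(sub$sir)) {
      p <- file.path(dir, paste0(tag, "_sir.nii.gz"))
      RNifti::writeNifti(sub$sir, p)
      paths$sir <- p
    }
    entries[[tag]] <- paths
  }
  man <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(seed = spec$seed, shape = spec$shape,
                            n_subjects = length(subjects),
                            subjects = entries),
                       man, auto_unbox = TRUE, digits = NA)
  invisible(man)
}

#' Load a phantom cohort from its manifest
#' @param manifest path to `manifest.json`.
#' @return List of subject lists (arrays restored; background T1 back to NA).
#' @export
read_subjects <- function(manifest) {
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  lapply(seq_len(man$n_subjects), function(s) {
    e <- man$subjects[[sprintf("sub%02d", s)]]
    labels <- .read_vol(e$labels)
    storage.mode(labels) <- "integer"
    t1 <- .read_vol(e$true_t1)
    t1[labels == tissue_codes["background"]] <- NA_real_
    gres <- lapply(unlist(e$gres), read_gre_pair)
    biased <- .read_vol(e$mp2rage_biased)
    biased[labels == tissue_codes["background"]] <- NA_real_
    list(subject = s, labels = labels, true_t1 = t1,
         b1 = .read_vol(e$b1),
         gres = gres,
         sir = if (!is.null(e$sir)) .read_vol(e$sir),
         ir_t1 = .read_vol(e$ir_t1),
         mp2rage_biased = biased)
  })
}
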