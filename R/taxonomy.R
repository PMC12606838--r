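#' Contraceptive method taxonomy
#'
#' A taxonomy partitions the contraceptive method codes the package accepts
#' into modern and traditional methods. The default modern set follows the
#' Hubacher--Trussell definition used by the international survey programs:
#' condoms, male and female sterilization, intrauterine devices, implants,
#' oral contraceptives, injectables, emergency pills, patches, diaphragms,
#' spermicidal agents, vaginal rings, and sponges. Methods absent from that
#' list (withdrawal, periodic abstinence/rhythm, the lactational amenorrhea
#' method, folk methods) default to traditional; the split is fully
#' user-configurable.
#'
#' @param modern character vector of modern method codes.
#' @param traditional character vector of traditional method codes. Must be
#'   disjoint from `modern`; `"none"` may not appear in either set.
#' @return An object of class `method_taxonomy`: a list with elements
#'   `modern` and `traditional`.
#' @examples
#' tax <- default_method_taxonomy()
#' classify_method(c("iud", "withdrawal", "none"), tax)
#' @export
method_taxonomy <- function(modern, traditional) {
  modern <- unique(as.character(modern))
  traditional <- unique(as.character(traditional))
  if ("none" %in% c(modern, traditional)) {
    stop("'none' denotes a non-user and may not be listed as a method")
  }
  overlap <- intersect(modern, traditional)
  if (length(overlap)) {
    stop("method codes listed as both modern and traditional: ",
         paste(overlap, collapse = ", "))
  }
  structure(list(modern = modern, traditional = traditional),
            class = "method_taxonomy")
}

#' @rdname method_taxonomy
#' @export
default_method_taxonomy <- function() {
  method_taxonomy(
    modern = c("condom", "female_condom", "sterilization_female",
               "sterilization_male", "iud", "implant", "pill", "injectable",
               "emergency_pill", "patch", "diaphragm", "spermicide",
               "vaginal_ring", "sponge"),
    traditional = c("withdrawal", "rhythm", "periodic_abstinence", "lam",
                    "other_traditional")
  )
}

#' @export
print.method_taxonomy <- function(x, ...) {
  cat("Contraceptive method taxonomy\n")
  cat("  modern (", length(x$modern), "): ",
      paste(x$modern, collapse = ", "), "\n", sep = "")
  cat("  traditional (", length(x$traditional), "): ",
      paste(x$traditional, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Classify contraceptive method codes
#'
#' Maps each method code to `"modern"`, `"traditional"`, or `"none"`
#' according to a taxonomy. Unknown codes raise an error naming the code:
#' silently treating an unrecognized method as non-use would deflate
#' prevalence estimates.
#'
#' @param method_code character vector of method codes (`"none"` for
#'   non-users). `NA` is treated as `"none"`.
#' @param taxonomy a [method_taxonomy()].
#' @return character vector with values in `c("modern", "traditional",
#'   "none")`, same length as `method_code`.
#' @export
classify_method <- function(method_code, taxonomy = default_method_taxonomy()) {
  stopifnot(inherits(taxonomy, "method_taxonomy"))
  method_code <- as.character(method_code)
  method_code[is.na(method_code)] <- "none"
  known <- c(taxonomy$modern, taxonomy$traditional, "none")
  bad <- setdiff(unique(method_code), known)
  if (length(bad)) {
    stop("unknown contraceptive method code(s): ",
         paste(bad, collapse = ", "),
         ". Add them to the taxonomy or recode them.")
  }
  out <- rep("none", length(method_code))
  out[method_code %in% taxonomy$modern] <- "modern"
  out[method_code %in% taxonomy$traditional] <- "traditional"
  out
}
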