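# User accounts for the writeback service. Writes are gated by login and
# password; reads are open. Passwords are never stored in clear: the user
# table holds a per-user random salt and the SHA-256 digest of salt+password.

#' Build a user account table
#'
#' @param logins Character vector of unique logins.
#' @param passwords Clear-text passwords (hashed immediately; only salted
#'   digests are kept).
#' @param display_names Optional display names; default the logins.
#' @return A tibble with columns `login`, `salt`, `digest`, `display_name`.
#' @examples
#' users <- wb_users(c("ana", "ben"), c("s3cret", "pa55"))
#' @export
wb_users <- function(logins, passwords, display_names = logins) {
  stopifnot(length(logins) == length(passwords), !anyDuplicated(logins))
  salts <- map_chr(logins, function(x) {
    paste(as.character(openssl::rand_bytes(8)), collapse = "")
  })
  tibble(
    login = as.character(logins),
    salt = salts,
    digest = purrr::map2_chr(salts, passwords, hash_password),
    display_name = as.character(display_names)
  )
}

hash_password <- function(salt, password) {
  as.character(openssl::sha256(paste0(salt, password)))
}

#' Read / write a user table as TSV
#'
#' The on-disk config format is four tab-separated columns: login, salt,
#' digest, display_name. Only salted digests touch the disk.
#' @param path TSV path.
#' @return `read_users()` returns the user tibble; `write_users()` returns
#'   `path` invisibly.
#' @export
read_users <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, colClasses = "character")
  stopifnot(identical(names(raw), c("login", "salt", "digest", "display_name")))
  as_tibble(raw)
}

#' @rdname read_users
#' @param users User tibble from [wb_users()].
#' @export
write_users <- function(users, path) {
  utils::write.table(users, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Authenticate a login/password pair against a user table
#'
#' @param users User tibble.
#' @param login,password Credentials as supplied by the client.
#' @return The login, to be used as `user_id` on version records.
#' @section Errors:
#' Unknown login, wrong password, or missing credentials signal a
#' `daswb_authentication_error` (surfaced as HTTP 401 by the service).
#' @export
authenticate <- function(users, login, password) {
  if (is.null(login) || is.null(password) || is.na(login) || !nzchar(login)) {
    stop_auth("missing credentials")
  }
  row <- users[users$login == login, ]
  if (nrow(row) != 1 || hash_password(row$salt, password) != row$digest) {
    stop_auth("unknown login or wrong password")
  }
  login
}
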