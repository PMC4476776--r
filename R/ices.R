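# ICES statistical rectangles: 0.5 deg latitude x 1 deg longitude reporting
# cells, rows numbered 01.. from 36N, columns lettered from 44W. The letter
# block A covers 44W-40W (digits 0-3 only); from 40W eastwards each letter
# spans 10 degrees of longitude (B, C, D, E, F, G, H, J, K, L, M; the letter
# I is not used) with the trailing digit giving the 1-degree step.

.ICES_LETTERS <- c("B", "C", "D", "E", "F", "G", "H", "J", "K", "L", "M")
.ICES_LAT <- c(36, 85.5)
.ICES_LON <- c(-44, 68.5)

#' Encode coordinates as an ICES statistical rectangle
#'
#' @param lat,lon numeric vectors of WGS84 coordinates (decimal degrees).
#'   Valid domain: latitude `[36, 85.5)`, longitude `[-44, 68.5)`; cells are
#'   half-open `[lo, hi)`, so a point on a shared edge belongs to the cell
#'   whose lower bound it equals.
#' @return character vector of rectangle codes such as `"44G1"`.
#' @seealso [ices_decode()]
#' @export
#' @examples
#' ices_encode(57.75, 11.5)  # "44G1", eastern Skagerrak
ices_encode <- function(lat, lon) {
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  bad <- !is.finite(lat) | !is.finite(lon) |
    lat < .ICES_LAT[1] | lat >= .ICES_LAT[2] |
    lon < .ICES_LON[1] | lon >= .ICES_LON[2]
  if (any(bad)) {
    stop("coordinates outside the ICES rectangle domain (36-85.5N, 44W-68.5E): ",
         paste0("(", lat[bad][1], ", ", lon[bad][1], ")"))
  }
  row <- floor((lat - 36) / 0.5) + 1
  west <- lon < -40
  code <- character(n)
  code[west] <- sprintf("%02dA%d", row[west], floor(lon[west] + 44))
  e <- !west
  letter <- .ICES_LETTERS[floor((lon[e] + 40) / 10) + 1]
  digit <- floor(lon[e] + 40) %% 10
  code[e] <- sprintf("%02d%s%d", row[e], letter, digit)
  code
}

#' Decode an ICES rectangle code to its bounds
#'
#' @param code character vector of rectangle codes (e.g. `"44G1"`).
#' @return data.frame with columns `code`, `lat_min`, `lat_max`, `lon_min`,
#'   `lon_max`; the rectangle is the half-open box
#'   `[lat_min, lat_max) x [lon_min, lon_max)`.
#' @export
ices_decode <- function(code) {
  code <- toupper(as.character(code))
  ok <- grepl("^[0-9]{2}[A-M][0-9]$", code)
  if (!all(ok)) stop("malformed ICES rectangle code: ", code[!ok][1])
  row <- as.integer(substr(code, 1, 2))
  letter <- substr(code, 3, 3)
  digit <- as.integer(substr(code, 4, 4))
  if (any(row < 1 | row > 99)) stop("ICES row out of range")
  lat_min <- 36 + (row - 1) * 0.5
  lon_min <- ifelse(letter == "A", -44 + digit,
                    -40 + (match(letter, .ICES_LETTERS) - 1) * 10 + digit)
  if (any(is.na(lon_min))) stop("invalid ICES column letter (I is not used)")
  if (any(letter == "A" & digit > 3)) stop("column A has digits 0-3 only")
  data.frame(code = code, lat_min = lat_min, lat_max = lat_min + 0.5,
             lon_min = lon_min, lon_max = lon_min + 1)
}
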