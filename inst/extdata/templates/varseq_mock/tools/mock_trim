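#!/bin/sh
# toy read trimmer: keeps reads whose sequence is at least --min-len long
IN=""; OUT=""; MIN=10
while [ $# -gt 0 ]; do
  case "$1" in
    -i) IN="$2"; shift 2 ;;
    -o) OUT="$2"; shift 2 ;;
    --min-len) MIN="$2"; shift 2 ;;
    *) shift ;;
  esac
done
[ -n "$IN" ] && [ -n "$OUT" ] || { echo "usage: mock_trim -i in -o out [--min-len n]" >&2; exit 2; }
[ -f "$IN" ] || { echo "mock_trim: no such file: $IN" >&2; exit 1; }
awk -v m="$MIN" 'length($2) >= m' "$IN" > "$OUT"
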