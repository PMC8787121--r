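#!/usr/bin/env python
"""Raster codec helper: decodes PNG/JPEG/BMP to PNM and back, and runs
in-memory JPEG round trips at given quality factors. All pixel maths
stays on the calling (R) side; this script only moves bytes through
Pillow's codecs."""

import io
import sys

from PIL import Image


def fail(msg):
    sys.stderr.write(msg + "\n")
    sys.exit(1)


def open_checked(path):
    try:
        im = Image.open(path)
        im.load()
    except Exception as exc:  # decode error surfaces to R with the path
        fail("cannot decode '%s': %s" % (path, exc))
    if im.mode in ("I", "I;16", "I;16B", "I;16L", "F"):
        fail("unsupported format: '%s' has bit depth > 8" % path)
    if im.mode == "P":
        im = im.convert("RGB")
    if im.mode == "LA":
        im = im.convert("L")
    if im.mode == "RGBA":
        im = im.convert("RGB")
    if im.mode not in ("L", "RGB", "1"):
        fail("unsupported format: '%s' mode %s" % (path, im.mode))
    if im.mode == "1":
        im = im.convert("L")
    return im


def cmd_decode(argv):
    src, dst = argv
    im = open_checked(src)
    im.save(dst, format="PPM")  # Pillow emits P5 for L, P6 for RGB
    sys.stdout.write(im.mode + "\n")


def cmd_encode(argv):
    src, dst = argv[:2]
    quality = int(argv[2]) if len(argv) > 2 else 90
    im = open_checked(src)
    kw = {}
    if dst.lower().endswith((".jpg", ".jpeg")):
        kw["quality"] = quality
    im.save(dst, **kw)


def cmd_jpegrt(argv):
    """jpegrt in.pgm out_prefix q1,q2,... -> out_prefix<q>.pgm per level."""
    src, prefix, levels = argv
    im = open_checked(src)
    if im.mode != "L":
        im = im.convert("L")
    for q in levels.split(","):
        q = int(q)
        buf = io.BytesIO()
        im.save(buf, format="JPEG", quality=q)
        buf.seek(0)
        back = Image.open(buf)
        back.load()
        back.convert("L").save("%s%d.pgm" % (prefix, q), format="PPM")


def main():
    if len(sys.argv) < 2:
        fail("usage: imtool.py {decode|encode|jpegrt} ...")
    cmd = sys.argv[1]
    handlers = {"decode": cmd_decode, "encode": cmd_encode,
                "jpegrt": cmd_jpegrt}
    if cmd not in handlers:
        fail("unknown command: " + cmd)
    handlers[cmd](sys.argv[2:])


if __name__ == "__main__":
    main()
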