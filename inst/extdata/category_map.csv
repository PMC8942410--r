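item,category,subcategory,conversion
oats,prebiotics,oats,1
banana,prebiotics,fruit,1
lentils,prebiotics,legumes,1
honey,prebiotics,honey,1
spinach,prebiotics,vegetables,1
yogurt,probiotics,fermented_dairy,1
kefir,probiotics,fermented_dairy,1
kimchi,probiotics,fermented_nondairy,1
miso,probiotics,fermented_nondairy,1
salmon,beneficial,omega3,1
olive_oil,beneficial,monounsaturated,1
chicken_breast,beneficial,lean_protein,1
tofu,beneficial,vegetable_protein,1
white_bread,adverse,wheat,1
soda,adverse,sugary_beverage,1
fried_food,adverse,processed_fried,1
corn,adverse,corn,1
diet_soda,adverse,artificial_sweeteners,1
processed_cheese,adverse,high_fat_processed,1
wine,alcohol,wine,1
beer,alcohol,beer,1
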